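#' Construct a 4-locus swarm genotype
#'
#' A genotype \verb{{b1,b2,b3;p}} holds the three state-specific collision
#' loci (0 = Stay, 1 = Leave; locus \code{b_i} is expressed while the robot is
#' in behavioral state \code{S_i}) and the pheromone-detection locus \code{p}
#' (0 = cannot detect, 1 = can detect).
#'
#' @param b1,b2,b3 collision-reaction alleles, each 0 or 1.
#' @param p pheromone-detection allele, 0 or 1.
#' @return An integer vector of class \code{swarm_genotype} with names
#'   \code{b1}, \code{b2}, \code{b3}, \code{p}.
#' @examples
#' genotype(1, 0, 1, 1)
#' as_genotype("{1,0,1;1}")
#' @export
genotype <- function(b1, b2, b3, p) {
  g <- c(b1 = as.integer(b1), b2 = as.integer(b2), b3 = as.integer(b3),
         p = as.integer(p))
  if (anyNA(g) || !all(g %in% c(0L, 1L)))
    stop("each locus must be exactly 0 or 1", call. = FALSE)
  structure(g, class = "swarm_genotype")
}

#' Coerce to a swarm genotype
#'
#' Accepts a \code{swarm_genotype}, a length-4 0/1 vector, or the bracket
#' notation string \verb{"{b1,b2,b3;p}"}.
#'
#' @param x object to coerce.
#' @return A \code{swarm_genotype}.
#' @export
as_genotype <- function(x) {
  if (inherits(x, "swarm_genotype")) return(x)
  if (is.character(x)) {
    if (length(x) != 1L) stop("as_genotype() takes a single genotype", call. = FALSE)
    m <- regmatches(x, regexec("^\\{([01]),([01]),([01]);([01])\\}$", trimws(x)))[[1]]
    if (length(m) != 5L)
      stop("cannot parse genotype '", x, "'; expected \"{b1,b2,b3;p}\" with 0/1 alleles",
           call. = FALSE)
    v <- as.integer(m[2:5])
    return(genotype(v[1], v[2], v[3], v[4]))
  }
  if (is.numeric(x) && length(x) == 4L) return(genotype(x[1], x[2], x[3], x[4]))
  stop("cannot coerce object of class '", paste(class(x), collapse = "/"),
       "' to a genotype", call. = FALSE)
}

#' Format a genotype in bracket notation
#' @param x a \code{swarm_genotype}.
#' @param ... unused.
#' @return The string \verb{"{b1,b2,b3;p}"}.
#' @export
format.swarm_genotype <- function(x, ...) {
  sprintf("{%d,%d,%d;%d}", x[[1]], x[[2]], x[[3]], x[[4]])
}

#' @export
print.swarm_genotype <- function(x, ...) {
  cat("<genotype ", format(x), ">\n", sep = "")
  invisible(x)
}

#' All 16 multilocus genotypes
#'
#' @return Character vector of the 16 genotype labels, ordered by the binary
#'   value of (b1, b2, b3, p), so \verb{"{0,0,0;0}"} is first and
#'   \verb{"{1,1,1;1}"} last. The position of a label in this vector is its
#'   canonical index (see \code{\link{genotype_index}}).
#' @export
all_genotypes <- function() {
  grid <- expand.grid(p = 0:1, b3 = 0:1, b2 = 0:1, b1 = 0:1)
  sprintf("{%d,%d,%d;%d}", grid$b1, grid$b2, grid$b3, grid$p)
}

#' Canonical index of a genotype
#'
#' @param g anything accepted by \code{\link{as_genotype}}.
#' @return Integer in 1..16: \code{1 + 8*b1 + 4*b2 + 2*b3 + p}.
#' @export
genotype_index <- function(g) {
  g <- as_genotype(g)
  1L + 8L * g[[1]] + 4L * g[[2]] + 2L * g[[3]] + g[[4]]
}

# 16 x 4 matrix of all genotypes in canonical index order (internal)
genotype_matrix <- function() {
  grid <- expand.grid(p = 0:1, b3 = 0:1, b2 = 0:1, b1 = 0:1)
  m <- as.matrix(grid[, c("b1", "b2", "b3", "p")])
  storage.mode(m) <- "integer"
  rownames(m) <- all_genotypes()
  m
}
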