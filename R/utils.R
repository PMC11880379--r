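#' @importFrom Matrix Matrix colSums rowSums rowMeans colMeans t readMM writeMM sparseMatrix
#' @importFrom methods as is
#' @importFrom stats cor hclust cutree kmeans loess predict mad median sd var
#'   rnbinom rpois rnorm runif rbeta quantile binom.test wilcox.test p.adjust
#'   pchisq pt setNames aggregate complete.cases
#' @importFrom utils head tail write.table read.table
NULL

# logistic rise of the shared chondrogenic programme along pseudotime
sigmoid_rise <- function(t, midpoint, scale = 0.1) {
  1 / (1 + exp(-(t - midpoint) / scale))
}

# transient lineage-specific TF wave
gauss_bump <- function(t, center, width = 0.25) {
  exp(-(t - center)^2 / (2 * width^2))
}

#' Test whether a set of leaves forms an exclusive clade of a dendrogram
#'
#' A label set is an exclusive clade if some internal node of the tree has
#' exactly that set as its leaves (or the set is a single leaf).
#'
#' @param hc an `hclust` object
#' @param members character vector of leaf labels
#' @return `TRUE` or `FALSE`
#' @export
is_exclusive_clade <- function(hc, members) {
  stopifnot(inherits(hc, "hclust"))
  labs <- hc$labels
  if (is.null(labs)) labs <- as.character(seq_len(nrow(hc$merge) + 1L))
  members <- unique(as.character(members))
  if (!all(members %in% labs)) return(FALSE)
  if (length(members) == 1L) return(TRUE)
  target <- sort(match(members, labs))
  node_sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    set <- integer(0)
    for (k in kids) {
      set <- c(set, if (k < 0) -k else node_sets[[k]])
    }
    node_sets[[i]] <- sort(set)
    if (length(set) == length(target) && all(node_sets[[i]] == target)) {
      return(TRUE)
    }
  }
  FALSE
}

# Dense numeric matrix view; accepts dgCMatrix or base matrix.
as_dense <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

# draw a deterministic child seed so operations never share streams
child_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
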