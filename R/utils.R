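# Internal helpers shared across modules.

#' @import EBImage
#' @importFrom stats median mad rlnorm rnorm rpois runif sd pf quantile
#'   kmeans chisq.test r2dtable setNames aggregate
#' @importFrom utils read.csv write.csv packageVersion
NULL

as_mat <- function(x) {
  x <- EBImage::imageData(x)
  dim(x) <- dim(x)[1:2]
  x
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so diagonally
# touching components are merged through an igraph union step.
label8 <- function(bw) {
  lab <- as_mat(EBImage::bwlabel(bw))
  n <- max(lab)
  if (n < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- list()
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    di <- off[1]; dj <- off[2]
    ri <- seq_len(nr - di)
    cj <- if (dj > 0) seq_len(nc - dj) else seq(1 - dj, nc)
    a <- lab[ri, cj, drop = FALSE]
    b <- lab[ri + di, cj + dj, drop = FALSE]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) pairs[[length(pairs) + 1L]] <- cbind(a[sel], b[sel])
  }
  if (!length(pairs)) return(lab)
  ed <- unique(do.call(rbind, pairs))
  g <- igraph::graph_from_edgelist(matrix(as.character(ed), ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, sum(!(as.character(seq_len(n)) %in%
                                       igraph::V(g)$name)),
                            name = setdiff(as.character(seq_len(n)),
                                           igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  map <- integer(n)
  map[as.integer(names(comp))] <- comp
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  relabel_sequential(out)
}

# Relabel nonzero labels to 1..N preserving order of first appearance by value.
relabel_sequential <- function(lab) {
  vals <- sort(unique(lab[lab > 0]))
  if (!length(vals)) return(lab)
  map <- integer(max(vals))
  map[vals] <- seq_along(vals)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

# Paint filled discs of radius r at integer centres onto a matrix (by value).
paint_discs <- function(mat, centres, r, values) {
  nr <- nrow(mat); nc <- ncol(mat)
  rr <- ceiling(r)
  off <- expand.grid(di = -rr:rr, dj = -rr:rr)
  off <- off[off$di^2 + off$dj^2 <= r^2, , drop = FALSE]
  for (i in seq_len(nrow(centres))) {
    pi <- round(centres[i, 1]) + off$di
    pj <- round(centres[i, 2]) + off$dj
    ok <- pi >= 1 & pi <= nr & pj >= 1 & pj <= nc
    mat[cbind(pi[ok], pj[ok])] <- values[i]
  }
  mat
}

gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  as_mat(EBImage::gblur(mat, sigma = sigma, boundary = "replicate"))
}

# Deterministic small-integer seed derived from a base seed and a string tag.
# All arithmetic in doubles to stay clear of 32-bit integer overflow.
derive_seed <- function(seed, tag) {
  u <- utf8ToInt(tag)
  h <- sum(u * seq_along(u)) %% 99991
  s <- (abs(as.numeric(seed)) %% 1000003) * 2003
  as.integer((s + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
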