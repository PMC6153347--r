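## Internal helpers: seeded RNG substreams, grid geometry, connected
## components on a 3D voxel grid, cosine similarity.

## Window centres (seconds post sentence onset) used throughout.
WINDOW_TIMES <- seq(2, 14, by = 2)

## Deterministic per-purpose seed derived from a master seed. Substreams keep
## the consumers of randomness independent of one another: adding bootstrap
## draws does not perturb the null permutations, etc. Result stays below
## .Machine$integer.max.
.substreamSeed <- function(seed, stream, index = 0L) {
  offsets <- c(simulate = 11L, bootstrap = 23L, null = 37L,
               groupperm = 53L, Rperm = 71L, generic = 89L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 48271 + off * 16807 + index * 127) %%
               2147483629)
}

## Evaluate expr with a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.coordToLin <- function(coord, dims) {
  coord[, 1L] + dims[1L] * (coord[, 2L] - 1L) +
    dims[1L] * dims[2L] * (coord[, 3L] - 1L)
}

## Neighbourhood offsets for 6-, 18- or 26-connectivity.
.connOffsets <- function(connectivity = 6L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1L,
                 "18" = nz >= 1L & nz <= 2L,
                 "26" = nz >= 1L)
  g[keep, , drop = FALSE]
}

## Vectorised union-find over an edge list: returns a root id per node.
.unionFind <- function(n, ea, eb) {
  parent <- seq_len(n)
  if (length(ea) == 0L) return(parent)
  repeat {
    pa <- parent[ea]; pb <- parent[eb]
    upd <- pa != pb
    if (!any(upd)) break
    hi <- pmax(pa, pb)[upd]; lo <- pmin(pa, pb)[upd]
    ## scatter-min: attach each larger root to the smallest partner root
    o <- order(hi, lo)
    f <- !duplicated(hi[o])
    tgt <- hi[o][f]
    parent[tgt] <- pmin(parent[tgt], lo[o][f])
    ## path compression to the root
    repeat {
      p2 <- parent[parent]
      if (identical(p2, parent)) break
      parent <- p2
    }
  }
  parent
}

#' Label connected components of a voxel set
#'
#' Partitions a set of voxels (given as linear indices into a 3D grid) into
#' connected components under face (6), edge (18) or corner (26)
#' connectivity. Neighbour pairs are found by hashing linear indices, and
#' components are merged with a vectorised union-find, so the cost scales
#' with the number of voxels in the set, not with the grid.
#'
#' @param idx integer vector of 1-based linear voxel indices.
#' @param dims integer(3), the grid dimensions.
#' @param connectivity one of 6, 18, 26.
#' @return integer vector parallel to `idx`: component id (1-based, ordered
#'   by first appearance in `idx`).
#' @examples
#' clusterLabels(c(1, 2, 30), c(3, 3, 3))  # 1 1 2
#' @export
clusterLabels <- function(idx, dims, connectivity = 6L) {
  idx <- as.integer(idx)
  n <- length(idx)
  if (n == 0L) return(integer(0))
  if (anyDuplicated(idx)) stop("duplicate voxel indices")
  coord <- arrayInd(idx, dims)
  offs <- .connOffsets(as.integer(connectivity))
  ## one direction per unordered neighbour pair suffices
  offs <- offs[offs[, 1L] > 0 |
                 (offs[, 1L] == 0 & offs[, 2L] > 0) |
                 (offs[, 1L] == 0 & offs[, 2L] == 0 & offs[, 3L] > 0),
               , drop = FALSE]
  ea <- eb <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    n1 <- coord[, 1L] + offs[k, 1L]
    n2 <- coord[, 2L] + offs[k, 2L]
    n3 <- coord[, 3L] + offs[k, 3L]
    valid <- n1 >= 1L & n1 <= dims[1L] & n2 >= 1L & n2 <= dims[2L] &
      n3 >= 1L & n3 <= dims[3L]
    nk <- n1 + dims[1L] * (n2 - 1L) + dims[1L] * dims[2L] * (n3 - 1L)
    m <- match(nk[valid], idx)
    hit <- which(!is.na(m))
    ea[[k]] <- which(valid)[hit]
    eb[[k]] <- m[hit]
  }
  root <- .unionFind(n, unlist(ea), unlist(eb))
  match(root, unique(root))
}

## Keep only voxels belonging to components of size >= minSize.
## Returns the surviving subset of idx (original order preserved).
.clusterFilter <- function(idx, dims, minSize, connectivity = 6L) {
  if (length(idx) == 0L) return(idx)
  comp <- clusterLabels(idx, dims, connectivity)
  sizes <- tabulate(comp)
  idx[sizes[comp] >= minSize]
}

## Cosine similarity; zero-norm vectors give 0 by convention.
.cosine <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

.logicalMap <- function(idx, dims) {
  m <- array(FALSE, dim = dims)
  m[idx] <- TRUE
  m
}
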