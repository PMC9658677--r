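#' Internal cavity detection by grid flood fill
#'
#' Lays a cubic grid over the structure's bounding box plus a margin. A voxel
#' is blocked when its center lies within (van der Waals radius + probe) of
#' any atom. Empty voxels reachable from the grid boundary are exterior
#' solvent; the remaining empty voxels are interior, and their 6-connected
#' components are the cavities. Each cavity is reported with its volume
#' (voxel count x voxel volume, in cubic Angstrom) and the residues lining
#' it (any atom within vdW radius + probe + grid spacing of a cavity voxel).
#'
#' @param s A [prot3d] object.
#' @param grid_spacing Grid step in Angstrom.
#' @param probe Probe radius in Angstrom.
#' @param min_voxels Drop components smaller than this many voxels
#'   (default 1 = keep all).
#' @return List of `cavity` objects sorted by decreasing volume, each with
#'   `voxels` (n x 3 centers), `volume` (A^3) and `lining` (data.frame of
#'   chain/resno/aa). Empty list when the structure has no cavity.
#' @export
find_cavities <- function(s, grid_spacing = 0.7, probe = 1.4,
                          min_voxels = 1L) {
  stopifnot(inherits(s, "prot3d"))
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- atom_radius(a$elesy)
  margin <- max(rad) + probe + 2 * grid_spacing
  gx <- seq(min(xyz[, 1]) - margin, max(xyz[, 1]) + margin, by = grid_spacing)
  gy <- seq(min(xyz[, 2]) - margin, max(xyz[, 2]) + margin, by = grid_spacing)
  gz <- seq(min(xyz[, 3]) - margin, max(xyz[, 3]) + margin, by = grid_spacing)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  blocked <- array(FALSE, dim = c(nx, ny, nz))
  for (i in seq_len(nrow(xyz))) {
    R <- rad[i] + probe
    ix <- which(abs(gx - xyz[i, 1]) <= R)
    iy <- which(abs(gy - xyz[i, 2]) <= R)
    iz <- which(abs(gz - xyz[i, 3]) <= R)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[i, 1])^2
    dy2 <- (gy[iy] - xyz[i, 2])^2
    dz2 <- (gz[iz] - xyz[i, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    blocked[ix, iy, iz] <- blocked[ix, iy, iz] | (d2 <= R^2)
  }
  ntot <- nx * ny * nz
  vix <- rep.int(seq_len(nx), times = ny * nz)
  viy <- rep.int(rep(seq_len(ny), each = nx), times = nz)
  viz <- rep(seq_len(nz), each = nx * ny)
  blocked_v <- as.logical(blocked)

  grow <- function(seeds, open) {
    # BFS over the 6-neighborhood restricted to `open` voxels
    state <- logical(ntot)
    seeds <- seeds[open[seeds] & !state[seeds]]
    state[seeds] <- TRUE
    frontier <- seeds
    offs <- list(c(-1L, 0L), c(1L, 0L), c(-nx, 1L), c(nx, 2L),
                 c(-nx * ny, 3L), c(nx * ny, 4L))
    while (length(frontier)) {
      nxt <- integer(0)
      for (o in offs) {
        cand <- frontier + o[1]
        keep <- switch(as.character(o[2]),
          "0" = if (o[1] < 0) vix[frontier] > 1L else vix[frontier] < nx,
          "1" = viy[frontier] > 1L, "2" = viy[frontier] < ny,
          "3" = viz[frontier] > 1L, "4" = viz[frontier] < nz)
        cand <- cand[keep]
        cand <- cand[open[cand] & !state[cand]]
        if (length(cand)) {
          state[cand] <- TRUE
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
    state
  }

  open <- !blocked_v
  boundary <- which((vix == 1L | vix == nx | viy == 1L | viy == ny |
                     viz == 1L | viz == nz) & open)
  exterior <- grow(boundary, open)
  interior <- open & !exterior
  cavities <- list()
  remaining <- which(interior)
  while (length(remaining)) {
    comp <- grow(remaining[1], interior)
    members <- which(comp)
    interior[members] <- FALSE
    remaining <- which(interior)
    if (length(members) < min_voxels) next
    centers <- cbind(gx[vix[members]], gy[viy[members]], gz[viz[members]])
    colnames(centers) <- c("x", "y", "z")
    # lining residues: atoms close to any cavity voxel
    lim <- rad + probe + grid_spacing
    near <- logical(nrow(xyz))
    for (k in seq_len(nrow(centers))) {
      d2 <- (xyz[, 1] - centers[k, 1])^2 + (xyz[, 2] - centers[k, 2])^2 +
            (xyz[, 3] - centers[k, 3])^2
      near <- near | (d2 <= lim^2)
    }
    lin <- unique(data.frame(chain = a$chain[near], resno = a$resno[near],
                             aa = a$aa[near], stringsAsFactors = FALSE))
    cavities[[length(cavities) + 1L]] <- structure(
      list(voxels = centers,
           volume = nrow(centers) * grid_spacing^3,
           lining = lin[order(lin$chain, lin$resno), , drop = FALSE]),
      class = "cavity")
  }
  ord <- order(vapply(cavities, `[[`, 0, "volume"), decreasing = TRUE)
  cavities[ord]
}

#' @export
print.cavity <- function(x, ...) {
  cat(sprintf("cavity: %.1f A^3 (%d voxels), lined by %d residues\n",
              x$volume, nrow(x$voxels), nrow(x$lining)))
  invisible(x)
}

#' Tabulate cavities as a data.frame
#'
#' @param cavities Result of [find_cavities()].
#' @return data.frame with `cavity`, `volume`, `n_voxels`, `lining` (comma
#'   separated residue numbers).
#' @export
cavity_report <- function(cavities) {
  if (!length(cavities))
    return(data.frame(cavity = integer(0), volume = numeric(0),
                      n_voxels = integer(0), lining = character(0)))
  data.frame(
    cavity = seq_along(cavities),
    volume = vapply(cavities, `[[`, 0, "volume"),
    n_voxels = vapply(cavities, function(cv) nrow(cv$voxels), 0L),
    lining = vapply(cavities, function(cv)
      paste(cv$lining$resno, collapse = ","), ""),
    stringsAsFactors = FALSE)
}
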