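#' Default 24-channel scalp montage
#'
#' A 10-20/10-10 subset with approximate 2-D scalp coordinates (unit head
#' circle, nose up) including the posterior alpha cluster channels Pz, P3,
#' P4 and POz. Channel adjacency is derived from Euclidean distance between
#' layout positions; the default radius yields a connected neighbor graph
#' with lateral and midline links comparable to template neighbor
#' definitions used for sensor-space cluster statistics.
#'
#' @param neighbor_radius Maximum inter-channel distance counted as
#'   adjacent (default 0.65 in layout units).
#' @return An object of class `montage`: list with `channels`
#'   (`data.frame` label/x/y) and `adjacency` (symmetric logical matrix).
#' @export
default_montage <- function(neighbor_radius = 0.65) {
  ch <- read.csv(text = "label,x,y
Fp1,-0.31,0.95
Fp2,0.31,0.95
F7,-0.81,0.59
F3,-0.45,0.55
Fz,0,0.52
F4,0.45,0.55
F8,0.81,0.59
FC1,-0.22,0.27
FC2,0.22,0.27
T7,-1,0
C3,-0.52,0
Cz,0,0
C4,0.52,0
T8,1,0
CP1,-0.22,-0.27
CP2,0.22,-0.27
P7,-0.81,-0.59
P3,-0.45,-0.55
Pz,0,-0.52
P4,0.45,-0.55
P8,0.81,-0.59
POz,0,-0.78
O1,-0.31,-0.95
O2,0.31,-0.95", stringsAsFactors = FALSE)
  make_montage(ch, neighbor_radius)
}

#' Build a montage from a channel layout table
#'
#' @param channels `data.frame` with columns `label`, `x`, `y`.
#' @param neighbor_radius Distance threshold for adjacency.
#' @return A `montage` object; see [default_montage()].
#' @export
make_montage <- function(channels, neighbor_radius = 0.65) {
  stopifnot(all(c("label", "x", "y") %in% names(channels)))
  if (anyDuplicated(channels$label)) stop("channel labels must be unique")
  d <- as.matrix(stats::dist(channels[, c("x", "y")]))
  adj <- d > 0 & d <= neighbor_radius
  dimnames(adj) <- list(channels$label, channels$label)
  structure(list(channels = channels, adjacency = adj,
                 neighbor_radius = neighbor_radius),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage: %d channels, %d adjacency edges>\n",
              nrow(x$channels), sum(x$adjacency) / 2))
  invisible(x)
}

#' Check a montage provides the parietal alpha cluster
#'
#' @param montage A `montage` object.
#' @param required Channel labels that must be present (default the
#'   posterior alpha cluster).
#' @return Invisibly `TRUE`; errors if any are missing.
#' @export
validate_montage <- function(montage,
                             required = c("Pz", "P3", "P4", "POz")) {
  stopifnot(inherits(montage, "montage"))
  missing_ch <- setdiff(required, montage$channels$label)
  if (length(missing_ch)) {
    stop("montage lacks required channel(s): ",
         paste(missing_ch, collapse = ", "))
  }
  if (!isTRUE(all(montage$adjacency == t(montage$adjacency)))) {
    stop("adjacency must be symmetric")
  }
  invisible(TRUE)
}

#' Read/write a montage as a plain-text layout file
#'
#' The layout file is a CSV of `label,x,y`; adjacency is recomputed from
#' the stored neighbor radius.
#' @param montage A `montage` object.
#' @param path File path.
#' @return `write_montage` returns the path invisibly; `read_montage`
#'   returns a `montage`.
#' @export
write_montage <- function(montage, path) {
  utils::write.csv(montage$channels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @param neighbor_radius Adjacency threshold used on re-read.
#' @export
read_montage <- function(path, neighbor_radius = 0.65) {
  make_montage(utils::read.csv(path, stringsAsFactors = FALSE),
               neighbor_radius)
}
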