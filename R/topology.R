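## Topological encoding: a plane's speech acts are laid out on a grid,
## themes (concatenations) along x, depth of elaboration along y. A theme
## may start at y > 1 when it emerges as an elaboration of an earlier one,
## leaving the cells above empty.

#' Encode a plane as a topological matrix
#'
#' Produces a character matrix with y as rows and x as columns; cell
#' `(y, x)` holds the content of the act addressed there, empty cells
#' `""`.
#'
#' @param d A validated `dialogue` or act table.
#' @param plane Plane index to encode (default 1).
#' @return Character matrix of class `topo_matrix` with `dimnames`
#'   `y = 1..max(y)`, `x = 1..max(x)`.
#' @export
#' @examples
#' mc <- read_transcript(system.file("extdata", "monte_cristo.tsv",
#'                                   package = "dialtk"))
#' m <- encode_matrix(mc)
#' m[6, 1]  # "Danglars"
encode_matrix <- function(d, plane = 1L) {
  acts <- acts_of(d)
  acts <- acts[acts$plane == plane, , drop = FALSE]
  if (nrow(acts) == 0L) stop("plane ", plane, " has no acts", call. = FALSE)
  key <- paste(acts$x, acts$y)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate address (x, y) = (", gsub(" ", ", ", dup),
         ") in plane ", plane, call. = FALSE)
  }
  m <- matrix("", nrow = max(acts$y), ncol = max(acts$x),
              dimnames = list(y = seq_len(max(acts$y)),
                              x = seq_len(max(acts$x))))
  m[cbind(acts$y, acts$x)] <- acts$content
  class(m) <- c("topo_matrix", class(m))
  m
}

#' @export
print.topo_matrix <- function(x, ...) {
  cat("<topo_matrix> ", nrow(x), " x ", ncol(x),
      " (y rows, x columns)\n", sep = "")
  print(unclass(x), quote = FALSE, ...)
  invisible(x)
}

#' Addresses occupied in a topological matrix
#'
#' Inverse of the encoding: recovers the set of occupied `(x, y)`
#' addresses (and their contents) from a matrix.
#'
#' @param m A `topo_matrix` (or character matrix, y rows x columns).
#' @return Data frame with columns `x`, `y`, `content`, ordered by
#'   `(x, y)`.
#' @export
matrix_addresses <- function(m) {
  hit <- which(m != "", arr.ind = TRUE, useNames = FALSE)
  out <- data.frame(x = as.integer(hit[, 2]),
                    y = as.integer(hit[, 1]),
                    content = m[hit], stringsAsFactors = FALSE)
  out[order(out$x, out$y), , drop = FALSE]
}

#' Occupancy probability matrix of a group of trajectories
#'
#' For each grid cell, the fraction of subjects whose trajectory passes
#' through that position at least once (repeat visits count once).
#'
#' @param trajectories Either a data frame with columns `subject_id`, `x`,
#'   `y` (rows in visit order), or a list of per-subject two-column
#'   matrices/data frames of `(x, y)` positions.
#' @param dims Optional `c(n_x, n_y)` grid extent; positions outside it
#'   are an error. Defaults to the maximum visited position.
#' @param group Group label carried on the result.
#' @return Numeric matrix (y rows, x columns) of class
#'   `occupancy_matrix`, values in `[0, 1]`, with attributes
#'   `n_subjects` and `group`.
#' @export
occupancy <- function(trajectories, dims = NULL, group = NA_character_) {
  if (is.data.frame(trajectories)) {
    stopifnot(all(c("subject_id", "x", "y") %in% names(trajectories)))
    traj <- split(trajectories[, c("x", "y")], trajectories$subject_id)
  } else if (is.list(trajectories)) {
    traj <- lapply(trajectories, function(t) {
      t <- as.data.frame(t)
      names(t)[1:2] <- c("x", "y")
      t
    })
  } else stop("trajectories must be a data frame or a list", call. = FALSE)
  if (!length(traj)) stop("empty group: no trajectories", call. = FALSE)
  all_pos <- do.call(rbind, traj)
  if (any(all_pos$x < 1L | all_pos$y < 1L))
    stop("trajectory positions must be >= 1", call. = FALSE)
  if (is.null(dims)) {
    dims <- c(max(all_pos$x), max(all_pos$y))
  } else if (any(all_pos$x > dims[1] | all_pos$y > dims[2])) {
    stop("trajectory position outside the declared ", dims[1], " x ",
         dims[2], " grid", call. = FALSE)
  }
  n <- length(traj)
  m <- matrix(0, nrow = dims[2], ncol = dims[1],
              dimnames = list(y = seq_len(dims[2]), x = seq_len(dims[1])))
  for (t in traj) {
    cells <- unique(cbind(t$y, t$x))
    m[cells] <- m[cells] + 1
  }
  m <- m / n
  structure(m, n_subjects = n, group = group,
            class = c("occupancy_matrix", class(m)))
}

#' @export
print.occupancy_matrix <- function(x, digits = 2, ...) {
  cat("<occupancy_matrix>",
      if (!is.na(attr(x, "group"))) paste0(" group = ", attr(x, "group")),
      ", n = ", attr(x, "n_subjects"), " subjects\n", sep = "")
  m <- matrix(round(as.numeric(x), digits), nrow(x), ncol(x),
              dimnames = dimnames(x))
  print(m, ...)
  invisible(x)
}
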