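#' Write trajectories to CSV
#'
#' Schema: `point_id, patient_id, label, t, x, y, z`, one row per sample,
#' `t` in seconds, label `-1` for unlabeled. Coordinates are serialized with
#' 12 significant digits so a write/read round trip preserves them well
#' beyond 9 significant digits.
#'
#' @param trajs List of [wm_trajectory()] objects (or a single one).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "wm_trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    TT <- nrow(tr$coords)
    data.frame(point_id = tr$point_id, patient_id = tr$patient_id,
               label = if (is.na(tr$label)) -1L else tr$label,
               t = sprintf("%.12g", (seq_len(TT) - 1) / tr$rate),
               x = sprintf("%.12g", tr$coords[, 1]),
               y = sprintf("%.12g", tr$coords[, 2]),
               z = sprintf("%.12g", tr$coords[, 3]),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Rows are grouped by `point_id` (order of first appearance) and sorted by
#' `t` within each point, so shuffled files are legal. Parse errors (missing
#' columns, duplicated time stamps within a point, non-finite coordinates)
#' name the offending row.
#'
#' @param path CSV file in the [write_trajectories()] schema.
#' @return List of [wm_trajectory()] objects.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("point_id", "patient_id", "label", "t", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  for (cc in c("t", "x", "y", "z")) df[[cc]] <- as.numeric(df[[cc]])
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z) |
                 !is.finite(df$t))
  if (length(bad))
    stop(sprintf("non-finite coordinate or time at row %d", bad[1] + 1L))
  ids <- unique(df$point_id)
  lapply(ids, function(id) {
    g <- df[df$point_id == id, , drop = FALSE]
    o <- order(g$t)
    g <- g[o, , drop = FALSE]
    dup <- which(duplicated(g$t))
    if (length(dup))
      stop(sprintf("duplicated time stamp within point '%s' (file row %d)",
                   id, as.integer(rownames(g)[dup[1]]) + 1L))
    rate <- 1 / stats::median(diff(g$t))
    lab <- g$label[1]
    wm_trajectory(cbind(g$x, g$y, g$z), rate = rate, point_id = id,
                  patient_id = g$patient_id[1],
                  label = if (lab < 0) NA_integer_ else as.integer(lab))
  })
}

#' Create a point-cloud object
#'
#' @param positions `n x 3` numeric matrix (mm).
#' @param labels Optional per-point labels (`0` TW, `1` HR, `NA` unlabeled).
#' @param rgb Optional `n x 3` integer matrix of colors in `[0, 255]`.
#' @return Object of class `wm_cloud`.
#' @export
wm_cloud <- function(positions, labels = NULL, rgb = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3 || nrow(positions) < 1)
    stop("positions must be a non-empty n x 3 matrix")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (!is.null(labels) && length(labels) != nrow(positions))
    stop("labels length must match positions")
  if (!is.null(rgb)) {
    rgb <- as.matrix(rgb)
    if (!all(dim(rgb) == c(nrow(positions), 3)))
      stop("rgb must be n x 3")
    if (any(rgb < 0 | rgb > 255)) stop("rgb channels must lie in [0, 255]")
  }
  structure(list(positions = unname(positions), labels = labels, rgb = rgb),
            class = "wm_cloud")
}

#' @export
print.wm_cloud <- function(x, ...) {
  cat(sprintf("<wm_cloud: %d points%s%s>\n", nrow(x$positions),
              if (!is.null(x$labels)) ", labeled" else "",
              if (!is.null(x$rgb)) ", colored" else ""))
  invisible(x)
}

#' Map RGB colors to wall-region labels
#'
#' Points with an apparent blue or red coloration mark the two wall classes,
#' but which color denotes TW and which HR must be stated explicitly via
#' `mapping` (there is no safe default). A channel is "dominant" when it
#' exceeds both other channels by at least `margin`; points with no dominant
#' red or blue channel are unlabeled.
#'
#' @param rgb `n x 3` matrix (or length-3 vector) with values in `[0, 255]`.
#' @param mapping Named character vector assigning classes to colors, e.g.
#'   `c(blue = "TW", red = "HR")`; both `red` and `blue` must be mapped, one
#'   to `"TW"` and the other to `"HR"`.
#' @param margin Dominance margin (default 50).
#' @return Integer vector: 0 (TW), 1 (HR) or NA (unlabeled).
#' @export
color_to_label <- function(rgb, mapping, margin = 50) {
  if (missing(mapping) || is.null(mapping))
    stop("'mapping' is required: state which of red/blue is TW and which HR")
  if (!setequal(names(mapping), c("red", "blue")) ||
      !setequal(unname(mapping), c("TW", "HR")))
    stop("mapping must assign 'red' and 'blue' to 'TW' and 'HR'")
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  rgb <- as.matrix(rgb)
  if (ncol(rgb) != 3) stop("rgb must have 3 channels")
  if (any(rgb < 0 | rgb > 255)) stop("rgb channels must lie in [0, 255]")
  to_int <- function(cls) if (cls == "TW") 0L else 1L
  out <- rep(NA_integer_, nrow(rgb))
  red_dom <- rgb[, 1] >= rgb[, 2] + margin & rgb[, 1] >= rgb[, 3] + margin
  blue_dom <- rgb[, 3] >= rgb[, 1] + margin & rgb[, 3] >= rgb[, 2] + margin
  out[red_dom] <- to_int(mapping[["red"]])
  out[blue_dom] <- to_int(mapping[["blue"]])
  out
}

#' Nearest-point label transfer
#'
#' Assigns to each point of the primary cloud the label of its
#' Euclidean-nearest point in the colored (labeled) cloud, emulating the
#' final step that fuses an intraoperatively colored point cloud with the
#' imaging-derived one. Ties are broken by the lowest colored-point index;
#' output order equals primary order. The transfer is idempotent.
#'
#' @param primary A [wm_cloud()] (labels ignored).
#' @param colored A [wm_cloud()] carrying `labels`, or `rgb` plus `mapping`.
#' @param mapping Passed to [color_to_label()] when `colored` has only
#'   colors.
#' @param margin Dominance margin for [color_to_label()].
#' @return The primary cloud with transferred `labels`.
#' @export
nearest_point_label_transfer <- function(primary, colored, mapping = NULL,
                                         margin = 50) {
  stopifnot(inherits(primary, "wm_cloud"), inherits(colored, "wm_cloud"))
  labs <- colored$labels
  if (is.null(labs)) {
    if (is.null(colored$rgb)) stop("colored cloud has neither labels nor rgb")
    labs <- color_to_label(colored$rgb, mapping, margin)
  }
  if (nrow(colored$positions) < 1) stop("colored cloud is empty")
  idx <- nearest_index(primary$positions, colored$positions)
  wm_cloud(primary$positions, labels = labs[idx], rgb = primary$rgb)
}

# Index of the Euclidean-nearest row of `ref` for each row of `query`;
# ties resolved to the lowest reference index. Chunked distance matrix.
nearest_index <- function(query, ref) {
  n <- nrow(query)
  out <- integer(n)
  rn <- rowSums(ref^2)
  chunk <- max(1L, floor(2e6 / nrow(ref)))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rn, "+") - 2 * tcrossprod(q, ref)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Write an ASCII PLY point cloud
#'
#' Vertex properties: `float x y z` plus `uchar red green blue` when the
#' cloud carries colors (or labels, which are rendered through `mapping`).
#'
#' @param cloud A [wm_cloud()].
#' @param path Output file.
#' @param mapping Optional label-to-color mapping (as in
#'   [color_to_label()]) used to render labels when no rgb is stored;
#'   unlabeled points are written gray (128,128,128).
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, mapping = NULL) {
  stopifnot(inherits(cloud, "wm_cloud"))
  n <- nrow(cloud$positions)
  rgb <- cloud$rgb
  if (is.null(rgb) && !is.null(cloud$labels) && !is.null(mapping)) {
    col_of <- function(cls) if (mapping[["red"]] == cls) c(255L, 0L, 0L)
      else c(0L, 0L, 255L)
    rgb <- t(vapply(cloud$labels, function(l) {
      if (is.na(l)) c(128L, 128L, 128L) else col_of(c("TW", "HR")[l + 1])
    }, integer(3)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property float x", "property float y", "property float z"),
             con)
  if (!is.null(rgb))
    writeLines(c("property uchar red", "property uchar green",
                 "property uchar blue"), con)
  writeLines("end_header", con)
  xyz <- apply(cloud$positions, 1, function(r)
    paste(sprintf("%.9g", r), collapse = " "))
  if (!is.null(rgb))
    xyz <- paste(xyz, apply(rgb, 1, paste, collapse = " "))
  writeLines(xyz, con)
  invisible(path)
}

#' Read an ASCII PLY point cloud
#'
#' Supports the subset written by [write_ply()]: ASCII format, a vertex
#' element with float `x y z` and optional uchar `red green blue`.
#'
#' @param path PLY file.
#' @return A [wm_cloud()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stop("not a PLY file: ", path)
  hend <- match("end_header", lines)
  if (is.na(hend)) stop("PLY header has no end_header")
  header <- lines[seq_len(hend)]
  if (!any(grepl("^format ascii", header)))
    stop("only ascii PLY is supported")
  vline <- grep("^element vertex ", header, value = TRUE)
  if (length(vline) != 1) stop("PLY must declare one vertex element")
  n <- as.integer(sub("^element vertex ", "", vline))
  props <- sub("^property \\S+ ", "", grep("^property ", header, value = TRUE))
  if (!identical(props[1:3], c("x", "y", "z")))
    stop("vertex element must start with properties x, y, z")
  has_rgb <- length(props) >= 6 &&
    identical(props[4:6], c("red", "green", "blue"))
  body <- lines[(hend + 1):(hend + n)]
  fields <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  pos <- matrix(as.numeric(fields[, 1:3]), ncol = 3)
  rgb <- if (has_rgb) matrix(as.integer(fields[, 4:6]), ncol = 3) else NULL
  wm_cloud(pos, rgb = rgb)
}
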