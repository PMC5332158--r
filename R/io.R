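# table and image readers/writers: plain CSV with header rows, lengths in
# micrometres and times in hours; image stacks as multi-frame grayscale TIFF

#' Write / read a lifespan table
#'
#' CSV columns: cell_id, generations_at_death, status, terminal_phenotype,
#' sibling_fate, defect_class.
#'
#' @param table Lifespan table.
#' @param path File path.
#' @return The path (write) or the table (read).
#' @export
write_lifespans <- function(table, path) {
  stopifnot(is.data.frame(table))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lifespans
#' @export
read_lifespans <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "generations_at_death", "status")
  if (!all(need %in% names(d)))
    stopf("lifespan CSV must have columns %s", paste(need, collapse = ", "))
  for (col in c("terminal_phenotype", "sibling_fate", "defect_class"))
    if (is.null(d[[col]])) d[[col]] <- "none"
  d
}

#' Write / read trajectories in long CSV form
#'
#' One row per (cell, time point): cell_id, time_h, length_um. Division
#' events and per-generation ground truth are written alongside.
#'
#' @param trajectories List of \code{cell_trajectory}.
#' @param path Output CSV path for the long trace table.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  long <- do.call(rbind, lapply(trajectories, function(tr)
    data.frame(cell_id = tr$cell_id, time_h = tr$times, length_um = tr$lengths)))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @param gen_path Output CSV path for the per-generation table.
#' @export
write_generations <- function(trajectories, gen_path) {
  gt <- generation_table(trajectories)
  write.csv(gt, gen_path, row.names = FALSE)
  invisible(gen_path)
}

#' Write / read a kymograph stack as multi-frame grayscale TIFF
#'
#' Intensities are clamped to [0, 1] on write. The ground-truth sidecar
#' (timestamps, applied shifts, rotation) is written as CSV next to the
#' TIFF when \code{truth_path} is given.
#'
#' @param stack A \code{kymograph_stack}.
#' @param path TIFF path.
#' @param truth_path Optional sidecar CSV path.
#' @return The path (write) or a \code{kymograph_stack} (read).
#' @export
write_stack <- function(stack, path, truth_path = NULL) {
  stopifnot(inherits(stack, "kymograph_stack"))
  nt <- dim(stack$frames)[3]
  frames <- lapply(seq_len(nt), function(t)
    pmin(pmax(stack$frames[, , t], 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  if (!is.null(truth_path)) {
    write.csv(data.frame(frame = seq_len(nt),
                         time_h = stack$timestamps,
                         shift_row = stack$truth$shifts[, 1],
                         shift_col = stack$truth$shifts[, 2],
                         rotation_deg = stack$truth$rotation_deg),
              truth_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_stack
#' @param imaging \code{imaging_params} describing the stack geometry
#'   (pixel size, centreline, notch); required to quantify a stack read
#'   from disk.
#' @export
read_stack <- function(path, imaging = imaging_params(), truth_path = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (t in seq_along(frames)) arr[, , t] <- frames[[t]]
  truth <- NULL
  timestamps <- seq_len(length(frames))
  if (!is.null(truth_path) && file.exists(truth_path)) {
    tr <- read.csv(truth_path)
    timestamps <- tr$time_h
    truth <- list(trajectory = NULL,
                  shifts = cbind(tr$shift_row, tr$shift_col),
                  rotation_deg = tr$rotation_deg[1])
  }
  structure(list(frames = arr, timestamps = timestamps, imaging = imaging,
                 truth = truth),
            class = "kymograph_stack")
}

#' Write a survival fit as JSON
#'
#' @param fit A \code{survival_fit}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "survival_fit"))
  obj <- list(kind = fit$kind,
              alpha = fit$coef[["alpha"]], beta = fit$coef[["beta"]],
              adjusted_r2 = fit$adjusted_r2, rls = fit$rls,
              n_cells = fit$n_cells, weighting = fit$weighting)
  if (!is.null(fit$ci))
    obj$ci <- list(alpha = as.numeric(fit$ci["alpha", ]),
                   beta = as.numeric(fit$ci["beta", ]),
                   rls = as.numeric(fit$ci["rls", ]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
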