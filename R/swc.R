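#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), whitespace
#' separated, `#` comments. An optional branchlet spine table
#' (`branchlet_id`, `length_um`, `n_spines`) attaches spine counts to the
#' morphology's terminal segments.
#'
#' @param path SWC file path.
#' @param spine_csv optional path to a branchlet spine-count CSV.
#' @return a [neuron_morphology()].
#' @export
read_swc <- function(path, spine_csv = NULL) {
  nodes <- read.table(path, comment.char = "#",
                      col.names = c("id", "type", "x", "y", "z",
                                    "radius", "parent"))
  spines <- if (!is.null(spine_csv)) read.csv(spine_csv) else NULL
  neuron_morphology(nodes, branchlet_spines = spines)
}

#' Write a morphology to SWC (plus optional branchlet spine CSV)
#'
#' @param morph a [neuron_morphology()].
#' @param path output SWC path.
#' @param spine_csv optional output path for the branchlet spine-count CSV
#'   (`branchlet_id`, `length_um`, `n_spines`).
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path, spine_csv = NULL) {
  stopifnot(inherits(morph, "neuron_morphology"))
  con <- file(path, "w")
  writeLines("# id type x y z radius parent", con)
  write.table(morph$nodes[, c("id", "type", "x", "y", "z", "radius", "parent")],
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  if (!is.null(spine_csv)) {
    write.csv(morph$branchlets[, c("branchlet_id", "length_um", "n_spines")],
              spine_csv, row.names = FALSE)
  }
  invisible(path)
}

#' Read/write an eyelid trace CSV (`time_ms`, `value_px`)
#'
#' @param path CSV path.
#' @param trace an [eyelid_trace()] (for writing).
#' @param frame_rate_hz frame rate to attach when reading; inferred from the
#'   timestamps when `NULL`.
#' @return an [eyelid_trace()] / `path` invisibly.
#' @export
read_trace_csv <- function(path, frame_rate_hz = NULL) {
  d <- read.csv(path)
  if (is.null(frame_rate_hz)) {
    frame_rate_hz <- 1000 / stats::median(diff(d$time_ms))
  }
  eyelid_trace(d$time_ms, d$value_px, frame_rate_hz)
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace)[, c("time_ms", "value_px")], path,
            row.names = FALSE)
  invisible(path)
}

#' Read/write a frame stack as multi-page TIFF
#'
#' Timestamps and ROI travel in a sidecar YAML file (`<path>.meta.yaml`)
#' since baseline TIFF holds only pixels.
#'
#' @param stack a [frame_stack()] (for writing).
#' @param path TIFF path.
#' @return a [frame_stack()] / `path` invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(i) stack$frames[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(timestamps_ms = stack$timestamps_ms,
                        roi = as.integer(stack$roi)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  frame_stack(frames, meta$timestamps_ms, meta$roi)
}
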