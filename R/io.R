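# Readers/writers: multi-page 16-bit TIFF stacks with YAML sidecar
# metadata, emitter-map CSV, YAML configurations.

#' Write a speckle stack to a multi-page TIFF
#'
#' One 16-bit page per frame. Values are scaled to the full uint16 range;
#' the scale and the grid are recorded in a YAML sidecar (`<path>.yaml`) so
#' the round trip recovers physical units up to the quantization step
#' (max abs error <= 0.5 scale units).
#'
#' @param stack a `speckle_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "speckle_stack"))
  mx <- max(stack$images)
  if (mx == 0) mx <- 1
  frames <- lapply(seq_len(stack$n_patterns), function(p)
    round(stack_frame(stack, p) / mx * 65535) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16, compression = "none")
  yaml::write_yaml(list(max_value = mx, grid = as.integer(stack$grid),
                        n_patterns = stack$n_patterns,
                        seed = if (is.na(stack$seed)) NULL else stack$seed),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a speckle stack written by [write_stack()]
#'
#' @param path TIFF path (the `<path>.yaml` sidecar must sit next to it).
#' @return a `speckle_stack`.
#' @export
read_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  grid <- as.integer(meta$grid)
  imgs <- vapply(frames, function(f) as.vector(f) * meta$max_value,
                 numeric(prod(grid)))
  if (ncol(as.matrix(imgs)) != meta$n_patterns)
    stop("frame count mismatch: sidecar says ", meta$n_patterns,
         ", file has ", length(frames))
  speckle_stack(as.matrix(imgs), grid,
                seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Write / read an emitter map as CSV
#'
#' Columns: id, row, col, brightness.
#' @param emitters an [emitter_map()].
#' @param path CSV path.
#' @return `path` invisibly / an `emitter_map`.
#' @export
write_emitters <- function(emitters, path) {
  utils::write.csv(as.data.frame(emitters), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emitters
#' @export
read_emitters <- function(path) {
  df <- utils::read.csv(path)
  emitter_map(cbind(df$row, df$col), df$brightness)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a named list (see [run_pipeline()]).
#' @param path YAML path.
#' @return `path` invisibly / a named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Write a displacement graph edge list as CSV
#'
#' Columns: i, j, du_row, du_col, score.
#' @param graph a `displacement_graph`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  utils::write.csv(graph$edges, path, row.names = FALSE)
  invisible(path)
}
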