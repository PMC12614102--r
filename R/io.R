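# Container I/O. The native containers are R objects (signal_set,
# demod_output) serialized with saveRDS; each carries a `description`
# attribute mirroring the self-descriptive dataset convention of the
# recording system. (An HDF5 binding is not available in the target
# library, so .rds stands in for the on-disk container format.)

#' Write / read a simulation or demodulation container
#'
#' @param x a `signal_set` or `demod_output`.
#' @param path output path (conventionally `.rds`).
#' @param description free-text description stored alongside the data.
#' @return `path` (write) or the object (read), invisibly annotated.
#' @export
write_container <- function(x, path, description = NULL) {
  if (!is.null(description)) attr(x, "description") <- description
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) readRDS(path)
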