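#' @importFrom stats rnorm rbinom plogis coef vcov qnorm qt pnorm pt setNames
#' @importFrom utils head modifyList
NULL

# Deterministic 31-bit child seed from a parent seed and a string tag.
# One global seed drives per-column / per-block / per-iteration streams so
# adding a covariate (or a block) never perturbs the other streams.
child_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  x <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(tag)) x <- (x * 31 + ch) %% 2147483647
  as.integer(x)
}

vdra_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "vdra_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

file_md5 <- function(path) unname(tools::md5sum(path))

# Matrix payload serialization: CSV body + JSON sidecar carrying dimensions,
# producer and a checksum of the body. These are the "files" the transfer
# fabric moves.
write_payload <- function(mat, dir, name, producer, kind, extra = list()) {
  csv <- file.path(dir, paste0(name, ".csv"))
  data.table::fwrite(data.table::as.data.table(as.matrix(mat)), csv,
                     col.names = TRUE)
  meta <- c(list(
    name = name, producer = producer, kind = kind,
    nrow = nrow(mat), ncol = ncol(mat), checksum = file_md5(csv)
  ), extra)
  sidecar <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  c(csv, sidecar)
}

read_payload <- function(dir, name) {
  csv <- file.path(dir, paste0(name, ".csv"))
  sidecar <- file.path(dir, paste0(name, ".json"))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  mat <- as.matrix(data.table::fread(csv))
  if (!identical(dim(mat), c(as.integer(meta$nrow), as.integer(meta$ncol))))
    vdra_error("vdra_format_error", sprintf(
      "payload '%s': dimensions do not match sidecar", name))
  list(matrix = mat, meta = meta)
}
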