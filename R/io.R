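#' Write / read a trace ensemble as a directory of delimited files
#'
#' Each trace is written as two-column tab-separated text
#' (`displacement_nm`, `conductance_G0`) with a `#`-prefixed JSON metadata
#' header; a `manifest.json` lists the files and shared acquisition
#' metadata.
#'
#' @param data long trace ensemble (`trace`, `z`, `g`).
#' @param dir output directory (created if needed).
#' @return `write_trace_dir()` returns `dir` invisibly; `read_trace_dir()`
#'   returns the long tibble with the `meta` attribute restored.
#' @export
write_trace_dir <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- attr(data, "meta")
  if (!"trace" %in% names(data)) data <- dplyr::mutate(data, trace = 1L)
  ids <- unique(data$trace)
  files <- sprintf("trace_%05d.tsv", ids)
  for (k in seq_along(ids)) {
    d <- data[data$trace == ids[k], c("z", "g")]
    path <- file.path(dir, files[k])
    hdr <- jsonlite::toJSON(c(list(trace = ids[k]), meta), auto_unbox = TRUE)
    writeLines(paste0("# ", hdr), path)
    readr::write_tsv(setNames(d, c("displacement_nm", "conductance_G0")),
                     path, append = TRUE, col_names = TRUE)
  }
  jsonlite::write_json(list(files = files, meta = meta),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_trace_dir
#' @export
read_trace_dir <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  out <- dplyr::bind_rows(purrr::imap(man$files, function(f, k) {
    d <- readr::read_tsv(file.path(dir, f), comment = "#",
                         show_col_types = FALSE)
    tibble::tibble(trace = k, z = d$displacement_nm, g = d$conductance_G0)
  }))
  attr(out, "meta") <- man$meta
  out
}

#' Write / read an I-V sweep ensemble
#'
#' Sweeps are stored as two-column tab-separated text (`bias_V`,
#' `current_A`), one file per sweep plus a manifest.
#'
#' @param data long sweep ensemble (`sweep`, `v`, `i`).
#' @param dir directory.
#' @export
write_iv_dir <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(data$sweep)
  files <- sprintf("iv_%05d.tsv", ids)
  for (k in seq_along(ids)) {
    d <- data[data$sweep == ids[k], c("v", "i")]
    readr::write_tsv(setNames(d, c("bias_V", "current_A")),
                     file.path(dir, files[k]))
  }
  jsonlite::write_json(list(files = files),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_iv_dir
#' @export
read_iv_dir <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  dplyr::bind_rows(purrr::imap(man$files, function(f, k) {
    d <- readr::read_tsv(file.path(dir, f), show_col_types = FALSE)
    tibble::tibble(sweep = k, v = d$bias_V, i = d$current_A)
  }))
}

#' Write / read duplex sequences as FASTA
#'
#' Thin wrappers over Biostrings.
#'
#' @param sequence base string, or for reading a FASTA path.
#' @param path file path.
#' @param name FASTA record name.
#' @return `read_duplex_fasta()` returns the first record as a character
#'   string.
#' @export
write_duplex_fasta <- function(sequence, path, name = "duplex") {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA IO")
  }
  x <- Biostrings::DNAStringSet(sequence)
  names(x) <- name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_duplex_fasta
#' @export
read_duplex_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA IO")
  }
  as.character(Biostrings::readDNAStringSet(path)[[1]])
}

#' Write / read a zipper trajectory as a delimited table
#'
#' Columns `time_s`, `z_tip_nm`, `n_open`, `force_pN`, with the run
#' parameters echoed into a JSON sidecar (`<path>.json`).
#'
#' @param traj a [kmc_run()] trajectory.
#' @param path file path (TSV).
#' @export
write_trajectory <- function(traj, path) {
  readr::write_tsv(
    tibble::tibble(time_s = traj$t, z_tip_nm = traj$z_tip,
                   n_open = traj$n_open, force_pN = traj$force), path)
  prm <- attr(traj, "params"); prot <- attr(traj, "protocol")
  jsonlite::write_json(
    list(sequence = attr(traj, "sequence"), n_bp = attr(traj, "n_bp"),
         termination = attr(traj, "termination"),
         params = unclass(prm), protocol = unclass(prot)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  out <- tibble::tibble(t = d$time_s, z_tip = d$z_tip_nm,
                        n_open = d$n_open, force = d$force_pN)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    js <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "sequence") <- js$sequence
    attr(out, "n_bp") <- js$n_bp
    attr(out, "termination") <- js$termination
  }
  class(out) <- c("zj_trajectory", class(out))
  out
}
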