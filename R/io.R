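#' Read and write streamlines in TCK format
#'
#' Minimal reader/writer for the MRtrix TCK track format: a text header
#' terminated by `END`, then little-endian Float32 point triplets with
#' `(NaN,NaN,NaN)` separating streamlines and `(Inf,Inf,Inf)` terminating
#' the file. Coordinates are in scanner/world mm.
#'
#' @param streamlines List of point matrices (mm).
#' @param path File path (conventionally `.tck`).
#' @return `read_tck` returns a list of point matrices; `write_tck` returns
#'   `path` invisibly.
#' @export
write_tck <- function(streamlines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    "mrtrix tracks\n",
    "datatype: Float32LE\n",
    "count: ", length(streamlines), "\n")
  # file_offset placeholder: header length is known once written; compute it
  offset_line <- function(off) paste0("file: . ", off, "\n")
  base_len <- nchar(header, type = "bytes") + nchar("END\n", type = "bytes")
  off <- base_len
  repeat {
    total <- base_len + nchar(offset_line(off), type = "bytes")
    if (total == off) break
    off <- total
  }
  writeChar(paste0(header, offset_line(off), "END\n"), con, eos = NULL)
  for (sl in streamlines) {
    writeBin(as.numeric(t(as.matrix(sl))), con, size = 4, endian = "little")
    writeBin(as.numeric(rep(NaN, 3)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3)), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  # locate the END terminator of the text header in the raw bytes
  pat <- charToRaw("END\n")
  hdr_end <- NA_integer_
  for (i in which(raw_all == pat[1])) {
    if (i + 3 <= length(raw_all) &&
        identical(raw_all[i:(i + 3)], pat)) { hdr_end <- i; break }
  }
  if (is.na(hdr_end)) {
    stop("not a TCK file (no END header terminator)", call. = FALSE)
  }
  header <- rawToChar(raw_all[seq_len(hdr_end - 1)])
  if (!grepl("^mrtrix tracks", header)) {
    stop("not a TCK file", call. = FALSE)
  }
  if (!grepl("Float32LE", header)) {
    stop("only Float32LE TCK supported", call. = FALSE)
  }
  fm <- regmatches(header, regexpr("file: \\. [0-9]+", header))
  offset <- as.integer(sub("file: \\. ", "", fm))
  vals <- readBin(raw_all[(offset + 1):length(raw_all)], "numeric",
                  n = (length(raw_all) - offset) / 4, size = 4,
                  endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  is_nan <- is.nan(pts[, 1])
  is_inf <- is.infinite(pts[, 1])
  breaks <- which(is_nan | is_inf)
  out <- list()
  start <- 1
  for (b in breaks) {
    if (b > start) out[[length(out) + 1]] <- pts[start:(b - 1), , drop = FALSE]
    start <- b + 1
    if (is_inf[b]) break
  }
  out
}

#' Read and write scalar maps as NIfTI-1
#'
#' Thin wrappers over RNifti keeping the voxel spacing in the NIfTI header.
#'
#' @param values 3D numeric array.
#' @param spacing Voxel spacing in mm (length 3).
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_scalar_map` returns a list `values`, `spacing`;
#'   `write_scalar_map` returns `path` invisibly.
#' @export
write_scalar_map <- function(values, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_scalar_map
#' @export
read_scalar_map <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))])
}

#' Read / write an FSL-dialect gradient scheme
#'
#' bval: one whitespace-separated row of b-values; bvec: three rows of
#' x, y, z components.
#'
#' @param scheme A [dwi_scheme()].
#' @param bval_path,bvec_path Paths to the sidecar text files.
#' @return `read_scheme` returns a `dwi_scheme`; `write_scheme` returns the
#'   paths invisibly.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "dwi_scheme"))
  writeLines(paste(scheme$bvals, collapse = " "), bval_path)
  writeLines(apply(t(scheme$bvecs), 1, paste, collapse = " "), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_scheme
#' @export
read_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) scan(text = l, quiet = TRUE))
  bvecs <- t(do.call(rbind, rows))
  dwi_scheme(bvals, bvecs)
}

#' Write a consensus segmentation as CSV
#'
#' Columns `streamline_id,subject_id,label,stability`.
#'
#' @param consensus A `consensus_segmentation`.
#' @param subject_id Per-streamline subject identifiers.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(consensus, subject_id, path) {
  stopifnot(inherits(consensus, "consensus_segmentation"))
  df <- data.frame(streamline_id = seq_along(consensus$labels),
                   subject_id = subject_id,
                   label = consensus$labels,
                   stability = consensus$stability)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
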