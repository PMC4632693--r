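#' Parse a FreeSurfer aseg.stats file
#'
#' Extracts left/right putamen volume and the estimated total
#' intracranial volume from the text of a FreeSurfer `aseg.stats` file:
#' a block of `# `-prefixed header lines containing a
#' `Measure EstimatedTotalIntraCranialVol` entry, followed by a
#' whitespace-delimited segmentation table with `StructName` and
#' `Volume_mm3` columns. Column positions are taken from the
#' `# TableCol`/`# ColHeaders` header lines, so reordered tables parse
#' identically; extra structures and extra header lines are ignored.
#'
#' @param text the file contents: either a single string or a character
#'   vector of lines.
#' @return A named list with `putamen_left_mm3`, `putamen_right_mm3`,
#'   and `icv_mm3`.
#' @seealso [read_aseg_stats()] for the file-path convenience wrapper.
#' @export
parse_aseg_stats <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  lines <- text
  header <- grepl("^#", lines)

  icv_line <- grep("^#\\s*Measure\\s+EstimatedTotalIntraCranialVol", lines)
  if (length(icv_line) == 0L) {
    stop("aseg.stats parse error: no 'Measure EstimatedTotalIntraCranialVol' line",
         call. = FALSE)
  }
  icv_fields <- trimws(strsplit(sub("^#\\s*", "", lines[icv_line[1L]]), ",")[[1L]])
  suppressWarnings(icv_vals <- as.numeric(icv_fields))
  if (all(is.na(icv_vals))) {
    stop(sprintf("aseg.stats parse error at line %d: malformed ICV measure",
                 icv_line[1L]), call. = FALSE)
  }
  icv <- icv_vals[which(!is.na(icv_vals))[1L]]

  # Column map: "# TableCol  <n>  ColHeader  <name>" lines take priority;
  # fall back to the "# ColHeaders ..." summary line, then to the
  # standard aseg layout (Volume_mm3 in col 4, StructName in col 5).
  col_of <- function(name) {
    tc <- regmatches(lines, regexec(
      paste0("^#\\s*TableCol\\s+(\\d+)\\s+ColHeader\\s+", name, "\\s*$"), lines))
    hit <- which(lengths(tc) == 2L)
    if (length(hit) > 0L) return(as.integer(tc[[hit[1L]]][2L]))
    ch <- grep("^#\\s*ColHeaders\\b", lines)
    if (length(ch) > 0L) {
      hdr <- strsplit(sub("^#\\s*ColHeaders\\s+", "", lines[ch[1L]]), "\\s+")[[1L]]
      pos <- match(name, hdr)
      if (!is.na(pos)) return(pos)
    }
    c(Volume_mm3 = 4L, StructName = 5L)[[name]]
  }
  vol_col <- col_of("Volume_mm3")
  name_col <- col_of("StructName")

  body_idx <- which(!header & nzchar(trimws(lines)))
  structure_volume <- function(struct) {
    for (i in body_idx) {
      fields <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      if (length(fields) >= max(vol_col, name_col) && fields[name_col] == struct) {
        suppressWarnings(vol <- as.numeric(fields[vol_col]))
        if (is.na(vol)) {
          stop(sprintf("aseg.stats parse error at line %d: malformed volume for %s",
                       i, struct), call. = FALSE)
        }
        return(vol)
      }
    }
    stop(sprintf("aseg.stats parse error: no '%s' row in segmentation table", struct),
         call. = FALSE)
  }

  list(putamen_left_mm3 = structure_volume("Left-Putamen"),
       putamen_right_mm3 = structure_volume("Right-Putamen"),
       icv_mm3 = icv)
}

#' Read putamen and intracranial volumes from an aseg.stats file
#'
#' @param path path to a FreeSurfer `aseg.stats` file.
#' @return See [parse_aseg_stats()].
#' @export
read_aseg_stats <- function(path) {
  if (!file.exists(path)) stop("aseg.stats file not found: ", path, call. = FALSE)
  parse_aseg_stats(readLines(path, warn = FALSE))
}
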