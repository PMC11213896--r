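#' Read a feature-by-sample omics matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds feature ids and whose
#' header row holds sample ids; `NA` marks missing (e.g. outlier-masked)
#' entries. Lines starting with `#` are provenance comments written by
#' [write_matrix()] and are skipped.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (features x samples) with dimnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#")
  lines <- lines[keep]
  if (length(lines) < 1L) stop("empty matrix file: ", path, call. = FALSE)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (length(unique(nfield)) != 1L) {
    bad <- which(nfield != nfield[1L])[1L]
    stop("ragged row at line ", which(keep)[bad], " of ", path, call. = FALSE)
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id(s) in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  feature_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(body, function(f) {
    suppressWarnings(as.numeric(replace(f[-1L], f[-1L] == "NA", NA)))
  }, numeric(length(sample_ids)))
  if (length(sample_ids) == 1L) vals <- matrix(vals, nrow = 1L)
  m <- t(vals)
  # any non-numeric, non-NA token produced an NA not present as literal "NA"
  raw_na <- t(vapply(body, function(f) f[-1L] == "NA",
                     logical(length(sample_ids))))
  if (length(sample_ids) == 1L) raw_na <- matrix(raw_na, ncol = 1L)
  bad_cell <- which(is.na(m) & !raw_na, arr.ind = TRUE)
  if (nrow(bad_cell) > 0L) {
    stop("non-numeric cell at line ", bad_cell[1L, 1L] + 1L, ", column ",
         bad_cell[1L, 2L] + 1L, " of ", path, call. = FALSE)
  }
  dimnames(m) <- list(feature_ids, sample_ids)
  m
}

#' Write a feature-by-sample omics matrix as TSV
#'
#' Values are formatted to 10 significant digits so a write/read round trip is
#' an identity for practical purposes; missing entries are written as `NA`.
#' A `#`-prefixed header comment records the producing stage and seed.
#'
#' @param m Numeric matrix (features x samples) with dimnames.
#' @param path Output path.
#' @param stage,seed Optional provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, stage = NULL, seed = NULL) {
  check_omics_matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t21subtypes stage=%s seed=%s",
                     stage %||% "unspecified",
                     seed %||% "unspecified"), con)
  writeLines(paste(c("feature_id", colnames(m)), collapse = "\t"), con)
  txt <- format(m, digits = 10, trim = TRUE, scientific = FALSE)
  txt[is.na(m)] <- "NA"
  writeLines(paste(rownames(m), apply(txt, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-delimited, fields are set name,
#' description, then member ids. Duplicate members are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @param keep_description Keep the description field? Default `TRUE`.
#' @return A named list; each element is a list with `name`, `description`
#'   and a character vector `members`.
#' @export
read_gmt <- function(path, keep_description = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields",
           call. = FALSE)
    }
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT set '", f[1L], "' has duplicate members; deduplicated",
              call. = FALSE)
      members <- unique(members)
    }
    out[[i]] <- list(name = f[1L],
                     description = if (keep_description) f[2L] else NA_character_,
                     members = members)
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
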