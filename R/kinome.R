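# kinome_summary: packaged kinome deletion/phenotype dataset and its
# headline summary statistics.

.KINOME_STATUSES <- c(
  "viable", "lethal", "viable_kinase_domain", "lethal_kinase_domain", "not_determined"
)
.KINOME_GROUPS <- c(
  "AGC", "CAMK", "CK1", "CMGC", "STE", "Other", "Unclassified", "Atypical"
)

#' Path to the packaged kinome dataset
#'
#' A tab-separated transcription of a published Aspergillus nidulans kinome
#' deletion survey: 131 kinase records with systematic id, name,
#' group/family classification path, deletion status and controlled-
#' vocabulary phenotype tags. The phenotype tag vocabulary (with the
#' original free-text phrasing each tag normalizes) ships alongside as
#' `phenotype_vocab.tsv`.
#'
#' @return file path of `kinome_table.tsv`.
#' @export
kinome_table_path <- function() {
  system.file("extdata", "kinome_table.tsv", package = "fungidel")
}

#' Phenotype tag vocabulary
#' @return data.frame with columns `tag`, `source_text`, `description`.
#' @export
phenotype_vocabulary <- function() {
  read.delim(system.file("extdata", "phenotype_vocab.tsv", package = "fungidel"),
             stringsAsFactors = FALSE)
}

#' Load a kinome table
#'
#' Validates the controlled vocabularies: `deletion_status` must be one of
#' viable, lethal, viable_kinase_domain, lethal_kinase_domain,
#' not_determined; `group_path` must be a slash-delimited path whose leading
#' token is one of AGC, CAMK, CK1, CMGC, STE, Other, Unclassified, Atypical;
#' phenotype tags must come from [phenotype_vocabulary()]; systematic ids
#' must be unique; the `nulls_not_generated` tag may only co-occur with a
#' lethal status. Errors cite the offending row number.
#'
#' @param path TSV path (defaults to the packaged fixture).
#' @return data.frame of class `fd_kinome_table` with columns
#'   `systematic_id`, `name`, `group_path`, `deletion_status`, `phenotypes`
#'   (semicolon-separated tags, possibly empty) and `is_ffk`.
#' @export
load_kinome_table <- function(path = kinome_table_path()) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = list(phenotypes = "character"))
  if (nrow(df) == 0L) fd_stop("fd_format_error", "empty kinome table")
  need <- c("systematic_id", "name", "group_path", "deletion_status", "phenotypes", "is_ffk")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    fd_stop("fd_format_error", sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$systematic_id)) {
    fd_stop("fd_format_error", sprintf(
      "duplicate systematic_id at row %d", which(duplicated(df$systematic_id))[1L]
    ))
  }
  vocab <- phenotype_vocabulary()$tag
  for (i in seq_len(nrow(df))) {
    if (!df$deletion_status[i] %in% .KINOME_STATUSES) {
      fd_stop("fd_format_error", sprintf(
        "row %d: unknown deletion_status '%s'", i, df$deletion_status[i]
      ))
    }
    lead <- strsplit(df$group_path[i], "/", fixed = TRUE)[[1L]][1L]
    if (is.na(lead) || !lead %in% .KINOME_GROUPS) {
      fd_stop("fd_format_error", sprintf(
        "row %d: malformed group_path '%s'", i, df$group_path[i]
      ))
    }
    tags <- .split_tags(df$phenotypes[i])
    bad <- setdiff(tags, vocab)
    if (length(bad)) {
      fd_stop("fd_format_error", sprintf(
        "row %d: unknown phenotype tag(s) %s", i, paste(bad, collapse = ", ")
      ))
    }
    if ("nulls_not_generated" %in% tags &&
        !df$deletion_status[i] %in% c("lethal", "lethal_kinase_domain")) {
      fd_stop("fd_format_error", sprintf(
        "row %d: nulls_not_generated on a non-lethal record", i
      ))
    }
  }
  df$is_ffk <- as.logical(df$is_ffk)
  class(df) <- c("fd_kinome_table", class(df))
  df
}

.split_tags <- function(x) {
  if (is.na(x) || x == "") character(0) else trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
}

#' Summarize a kinome table
#'
#' Headline statistics of the deletion survey. Deleted genes exclude
#' `not_determined` records; essential = lethal statuses (whole-ORF or
#' kinase-domain-only); non-essential-with-phenotype counts viable records
#' carrying at least one phenotype tag; terminal-phenotype-defined counts
#' essential records whose nulls could be recovered from heterokaryons
#' (i.e. not tagged `nulls_not_generated`). Group counts are keyed by the
#' leading group token, with sub-tallies for the histidine kinases
#' (Atypical/HisK), the SRPK expansion (CMGC/SRPK) and the filamentous
#' fungal kinases (Ffk).
#'
#' @param records an `fd_kinome_table` from [load_kinome_table()].
#' @return list of class `fd_kinome_summary`.
#' @export
summarize_kinome <- function(records) {
  stopifnot(nrow(records) > 0L)
  st <- records$deletion_status
  essential <- st %in% c("lethal", "lethal_kinase_domain")
  viable <- st %in% c("viable", "viable_kinase_domain")
  nd <- st == "not_determined"
  n_total <- nrow(records)
  n_deleted <- sum(!nd)
  n_essential <- sum(essential)
  n_nonessential <- sum(viable)
  tags <- lapply(records$phenotypes, .split_tags)
  has_tag <- vapply(tags, length, integer(1)) > 0L
  n_with_phen <- sum(viable & has_tag)
  nng <- vapply(tags, function(t) "nulls_not_generated" %in% t, logical(1))
  n_terminal <- sum(essential & !nng)
  lead <- vapply(strsplit(records$group_path, "/", fixed = TRUE), `[[`, character(1), 1L)
  group_counts <- vapply(.KINOME_GROUPS, function(g) sum(lead == g), integer(1))
  subgroup_counts <- c(
    `Atypical/HisK` = sum(startsWith(records$group_path, "Atypical/HisK")),
    `CMGC/SRPK` = sum(startsWith(records$group_path, "CMGC/SRPK")),
    Ffk = sum(records$is_ffk)
  )
  structure(
    list(
      n_total = n_total,
      n_deleted = n_deleted,
      n_essential = n_essential,
      pct_essential = round(100 * n_essential / n_deleted, 1),
      n_nonessential = n_nonessential,
      n_nonessential_with_phenotype = n_with_phen,
      n_terminal_phenotype_defined = n_terminal,
      group_counts = group_counts,
      subgroup_counts = subgroup_counts
    ),
    class = "fd_kinome_summary"
  )
}

#' @export
print.fd_kinome_summary <- function(x, ...) {
  cat(sprintf("Kinome summary: %d kinases, %d deleted\n", x$n_total, x$n_deleted))
  cat(sprintf(
    "  essential: %d (%.1f%%), terminal phenotype defined for %d\n",
    x$n_essential, x$pct_essential, x$n_terminal_phenotype_defined
  ))
  cat(sprintf(
    "  non-essential: %d, with >=1 phenotype: %d\n",
    x$n_nonessential, x$n_nonessential_with_phenotype
  ))
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_counts), x$group_counts), collapse = " "), "\n")
  cat("  sub-tallies:", paste(sprintf("%s=%d", names(x$subgroup_counts), x$subgroup_counts), collapse = " "), "\n")
  invisible(x)
}

#' Write a kinome summary as JSON
#' @param summary an `fd_kinome_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kinome_summary <- function(summary, path) {
  jsonlite::write_json(
    list(
      n_total = summary$n_total, n_deleted = summary$n_deleted,
      n_essential = summary$n_essential, pct_essential = summary$pct_essential,
      n_nonessential = summary$n_nonessential,
      n_nonessential_with_phenotype = summary$n_nonessential_with_phenotype,
      n_terminal_phenotype_defined = summary$n_terminal_phenotype_defined,
      group_counts = as.list(summary$group_counts),
      subgroup_counts = as.list(summary$subgroup_counts)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
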