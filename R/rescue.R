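# rescue: classify transformants from plate growth + diagnostic PCR allele
# calls, and aggregate per-gene essentiality calls (heterokaryon rescue).

#' Transformant observation
#'
#' One primary transformant's plate-level evidence: colony formation from
#' streaked conidia on selective and non-selective media, the alleles its
#' diagnostic PCR detected, and whether single-colony purification on
#' selective medium succeeded (streak-stable haploid).
#'
#' @param transformant_id,gene_id identifiers.
#' @param grows_selective,grows_nonselective logical colony formation flags.
#' @param alleles_detected character subset of `c("wt", "null")`.
#' @param streak_stable_haploid logical.
#' @return list of class `fd_observation`.
#' @export
transformant_observation <- function(transformant_id, gene_id,
                                     grows_selective, grows_nonselective,
                                     alleles_detected, streak_stable_haploid) {
  alleles_detected <- sort(unique(alleles_detected))
  if (length(alleles_detected) && !all(alleles_detected %in% c("wt", "null"))) {
    fd_stop("fd_validation_error", "alleles_detected must be a subset of {wt, null}")
  }
  if (isTRUE(streak_stable_haploid) && !isTRUE(grows_selective)) {
    fd_stop("fd_validation_error", sprintf(
      "%s: streak-stable without selective growth is contradictory", transformant_id
    ))
  }
  if ((isTRUE(grows_selective) || isTRUE(grows_nonselective)) && !length(alleles_detected)) {
    fd_stop("fd_validation_error", sprintf(
      "%s: growth observed but no allele detected", transformant_id
    ))
  }
  structure(
    list(
      transformant_id = transformant_id, gene_id = gene_id,
      grows_selective = isTRUE(grows_selective),
      grows_nonselective = isTRUE(grows_nonselective),
      alleles_detected = alleles_detected,
      streak_stable_haploid = isTRUE(streak_stable_haploid)
    ),
    class = "fd_observation"
  )
}

#' Classify a single transformant
#'
#' Decision table:
#' * grows on both media, only the null allele detected, streak-stable:
#'   `haploid_null` (the gene is dispensable);
#' * grows non-selectively but conidia cannot form colonies on selective
#'   medium, both alleles detected: `heterokaryon` (a lethal deletion
#'   rescued by untransformed nuclei);
#' * streak-stable on selective medium with both alleles: `diploid`
#'   (formed during transformation; discarded from evidence);
#' * streak-stable with only the wild-type allele: `ectopic_integrant`
#'   (the marker integrated elsewhere);
#' * anything else: `inconclusive`.
#'
#' @param obs an [transformant_observation()].
#' @return one of `"haploid_null"`, `"heterokaryon"`, `"diploid"`,
#'   `"ectopic_integrant"`, `"inconclusive"`.
#' @export
classify_transformant <- function(obs) {
  stopifnot(inherits(obs, "fd_observation"))
  al <- obs$alleles_detected
  both <- setequal(al, c("wt", "null"))
  if (obs$grows_selective && obs$grows_nonselective &&
      identical(al, "null") && obs$streak_stable_haploid) {
    return("haploid_null")
  }
  if (!obs$grows_selective && obs$grows_nonselective && both) {
    return("heterokaryon")
  }
  if (obs$streak_stable_haploid && both) {
    return("diploid")
  }
  if (obs$streak_stable_haploid && identical(al, "wt")) {
    return("ectopic_integrant")
  }
  "inconclusive"
}

#' Aggregate transformant evidence into a per-gene essentiality call
#'
#' Diploids are excluded from evidence. Any verified haploid null forces
#' `non_essential`; at least one heterokaryon with no stable haploid null
#' gives `essential`; otherwise `undetermined`. Ectopic integrants are
#' neutral evidence.
#'
#' @param observations list of [transformant_observation()] for one gene.
#' @param min_transformants minimum number of observations required
#'   (default 6 independent transformants).
#' @return list of class `fd_gene_call` with `gene_id`, `essentiality`
#'   (`"essential"`, `"non_essential"` or `"undetermined"`) and `evidence`
#'   (character vector of per-transformant classifications).
#' @export
call_gene <- function(observations, min_transformants = 6L) {
  if (!length(observations)) {
    fd_stop("fd_validation_error", "no observations supplied")
  }
  gene_ids <- unique(vapply(observations, `[[`, character(1), "gene_id"))
  if (length(gene_ids) != 1L) {
    fd_stop("fd_validation_error", "observations span more than one gene")
  }
  if (length(observations) < min_transformants) {
    fd_stop("fd_validation_error", sprintf(
      "%s: %d observation(s) < required %d transformants",
      gene_ids, length(observations), min_transformants
    ))
  }
  cls <- vapply(observations, classify_transformant, character(1))
  informative <- cls[cls != "diploid"]
  essentiality <- if (any(informative == "haploid_null")) {
    "non_essential"
  } else if (any(informative == "heterokaryon")) {
    "essential"
  } else {
    "undetermined"
  }
  structure(
    list(gene_id = gene_ids, essentiality = essentiality, evidence = cls),
    class = "fd_gene_call"
  )
}

#' @export
print.fd_gene_call <- function(x, ...) {
  cat(sprintf(
    "<gene call %s> %s (%s)\n", x$gene_id, x$essentiality,
    paste(sprintf("%s x%d", names(table(x$evidence)), table(x$evidence)), collapse = ", ")
  ))
  invisible(x)
}

#' Read transformant observations from TSV
#'
#' Expected columns: `transformant_id`, `gene_id`, `grows_selective`,
#' `grows_nonselective`, `alleles_detected` (comma-separated subset of
#' `wt,null`; empty allowed for no-growth rows), `streak_stable_haploid`.
#'
#' @param path TSV path.
#' @return list of [transformant_observation()].
#' @export
read_observations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = list(alleles_detected = "character"))
  need <- c("transformant_id", "gene_id", "grows_selective", "grows_nonselective",
            "alleles_detected", "streak_stable_haploid")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    fd_stop("fd_format_error", sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  }
  lapply(seq_len(nrow(df)), function(i) {
    al <- df$alleles_detected[i]
    al <- if (is.na(al) || al == "") character(0) else strsplit(al, ",", fixed = TRUE)[[1L]]
    transformant_observation(
      df$transformant_id[i], df$gene_id[i],
      as.logical(df$grows_selective[i]), as.logical(df$grows_nonselective[i]),
      trimws(al), as.logical(df$streak_stable_haploid[i])
    )
  })
}

#' Write observations to TSV
#' @param observations list of [transformant_observation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  df <- data.frame(
    transformant_id = vapply(observations, `[[`, character(1), "transformant_id"),
    gene_id = vapply(observations, `[[`, character(1), "gene_id"),
    grows_selective = vapply(observations, `[[`, logical(1), "grows_selective"),
    grows_nonselective = vapply(observations, `[[`, logical(1), "grows_nonselective"),
    alleles_detected = vapply(observations, function(o) paste(o$alleles_detected, collapse = ","), character(1)),
    streak_stable_haploid = vapply(observations, `[[`, logical(1), "streak_stable_haploid"),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene calls as TSV and/or JSON
#'
#' @param calls list of `fd_gene_call`.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, a data.frame of the calls.
#' @export
write_gene_calls <- function(calls, tsv_path = NULL, json_path = NULL) {
  df <- data.frame(
    gene_id = vapply(calls, `[[`, character(1), "gene_id"),
    essentiality = vapply(calls, `[[`, character(1), "essentiality"),
    evidence = vapply(calls, function(x) paste(x$evidence, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(tsv_path)) write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) jsonlite::write_json(df, json_path, auto_unbox = TRUE, digits = NA)
  invisible(df)
}
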