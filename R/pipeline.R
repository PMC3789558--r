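## Orchestration: configuration handling, the scan -> families -> census ->
## evolve -> capture pipeline, artifact writing, and summary reporting.

#' Full pipeline configuration with defaults
#'
#' Nested parameter list covering every stage. All thresholds appear as named
#' keys: family_t = 0.80 and family_w = 30 (terminal-signature family rule),
#' evalue_max = 1e-6 / min_len = 80 / min_id = 0.80 (copy census), est_id =
#' 0.99 / est_evalue = 1e-10 (transcript matching), e_same = 1e-10 /
#' e_other = 1e-5 (capture), r = 1.56e-8 (neutral rate).
#'
#' @param seed RNG seed recorded in the manifest.
#' @return nested configuration list.
#' @export
default_params <- function(seed = 1L) {
  list(seed = as.integer(seed),
       end = end_params(),
       cluster = cluster_params(),
       census = census_params(),
       capture = capture_params(),
       evolution = list(r = 1.56e-8, band = 64L),
       naming = list(prefix = "SynHel"))
}

#' Validate a configuration against the default template
#'
#' Unknown keys (at any nesting level) are rejected; supplied keys override
#' defaults; missing keys keep their defaults.
#'
#' @param config partial configuration list.
#' @return completed configuration.
#' @export
validate_params <- function(config = list()) {
  merge1 <- function(template, given, path = "") {
    unknown <- setdiff(names(given), names(template))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (k in names(given)) {
      if (is.list(template[[k]]) && !is.null(names(template[[k]])))
        template[[k]] <- merge1(template[[k]], given[[k]],
                                paste0(path, k, "."))
      else template[[k]] <- given[[k]]
    }
    template
  }
  merge1(default_params(), config)
}

#' Read a YAML configuration file
#' @param path YAML file with (a subset of) [default_params()] keys.
#' @return validated configuration.
#' @export
read_params <- function(path) {
  validate_params(yaml::read_yaml(path))
}

atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".partial")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Percentage ratio helper
#'
#' `100 * num / den`, the arithmetic used for all summary ratios (e.g. the
#' fraction of intact elements with captured fragments).
#'
#' @param num,den numerator and denominator.
#' @param digits rounding (default 1 decimal, as printed in reports).
#' @return percentage.
#' @export
ratio_percent <- function(num, den, digits = 1L) {
  round(100 * num / den, digits)
}

#' Run the full identification + analysis pipeline
#'
#' Stages: end-structure scan, family building (clustering, consensus,
#' boundaries), genome census, insertion dating / diversity, and (when a
#' protein set is supplied) gene-capture analysis. Artifacts are written
#' atomically to `outdir` together with a manifest (parameters + seed).
#'
#' @param genome path to a genome FASTA, or a named character vector.
#' @param outdir output directory.
#' @param config configuration (see [validate_params()]).
#' @param te_library optional known-TE library (named vector or FASTA path).
#' @param proteins optional protein set for capture analysis.
#' @return list with all in-memory results (hits, elements, families, calls,
#'   reports, ages, diversity, capture) and the artifact paths.
#' @export
run_all <- function(genome, outdir, config = default_params(),
                    te_library = NULL, proteins = NULL) {
  if (is.character(genome) && length(genome) == 1 && is.null(names(genome))) {
    if (!file.exists(genome))
      stop("genome file not found: ", genome)
    genome <- read_fasta(genome)
  }
  if (is.character(te_library) && length(te_library) == 1 &&
      is.null(names(te_library)) && file.exists(te_library))
    te_library <- read_fasta(te_library)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  set.seed(cfg$seed)

  message("[1/5] scanning for end structures")
  hits <- scan_genome_ends(genome, params = cfg$end)

  message("[2/5] clustering and building consensus elements (",
          nrow(hits), " candidates)")
  fam_build <- build_families(hits, genome, params = cfg$cluster)
  families <- name_families(fam_build$elements, te_library = te_library,
                            prefix = cfg$naming$prefix, params = cfg$census)

  message("[3/5] genome census (", length(families), " families)")
  calls <- census_genome(families, genome, params = cfg$census)
  reports <- do.call(rbind, lapply(families, function(f)
    family_report(f, calls[calls$family == f$name, , drop = FALSE], genome)))

  message("[4/5] dating and diversity")
  ages <- date_copies(calls, families, genome, r = cfg$evolution$r,
                      band = cfg$evolution$band)
  diversity <- lapply(families, function(f) {
    fc <- calls[calls$family == f$name & calls$kind == "copy", , drop = FALSE]
    if (nrow(fc) < 3) return(NULL)
    aligned <- aligned_family_copies(fc, f$consensus, genome,
                                     band = cfg$evolution$band)
    md <- mismatch_distribution(aligned)
    list(family = f$name, hist = md$hist, diffs = md$diffs,
         modality = if (length(md$diffs) >= 10) classify_modality(md)
                    else NA_character_)
  })
  diversity <- Filter(Negate(is.null), diversity)

  capture <- NULL
  if (!is.null(proteins) && length(proteins)) {
    message("[5/5] capture analysis")
    intact <- calls[calls$intact, , drop = FALSE]
    el_seqs <- vapply(seq_len(nrow(intact)), function(i) {
      s <- oriented_seq(genome[[intact$seq_id[i]]], intact$strand[i])
      n <- nchar(genome[[intact$seq_id[i]]])
      sl <- if (intact$strand[i] == "+") c(intact$start[i], intact$end[i])
            else c(n - intact$end[i], n - intact$start[i])
      substr(s, sl[1] + 1L, sl[2])
    }, character(1))
    names(el_seqs) <- sprintf("%s:%d-%d", intact$seq_id, intact$start,
                              intact$end)
    capture <- capture_census(el_seqs, proteins, params = cfg$capture)
  } else message("[5/5] capture analysis skipped (no protein input)")

  ## ---- artifacts ----
  paths <- list(
    hits = file.path(outdir, "hits.gff3"),
    families = file.path(outdir, "families.fa"),
    copies = file.path(outdir, "copies.gff3"),
    report = file.path(outdir, "report.tsv"),
    ages = file.path(outdir, "ages.tsv"),
    manifest = file.path(outdir, "manifest.yaml"))
  if (nrow(hits))
    atomic_write(function(p) write_gff3(
      hits, p, type = "repeat_region",
      extra_cols = c("stem_len", "loop_len", "mismatches")), paths$hits)
  if (length(families))
    atomic_write(function(p) write_fasta(
      stats::setNames(vapply(families, `[[`, character(1), "consensus"),
                      vapply(families, `[[`, character(1), "name")), p),
      paths$families)
  if (nrow(calls))
    atomic_write(function(p) write_gff3(
      calls, p, type = "dispersed_repeat",
      extra_cols = c("family", "kind", "intact", "identity")), paths$copies)
  atomic_write(function(p) utils::write.table(
    reports, p, sep = "\t", quote = FALSE, row.names = FALSE), paths$report)
  atomic_write(function(p) utils::write.table(
    ages, p, sep = "\t", quote = FALSE, row.names = FALSE), paths$ages)
  atomic_write(function(p) yaml::write_yaml(
    list(package = "helitronscan",
         version = as.character(utils::packageVersion("helitronscan")),
         seed = cfg$seed, params = strip_for_yaml(cfg)), p), paths$manifest)

  list(hits = hits, elements = fam_build$elements,
       rejections = fam_build$rejections, families = families,
       calls = calls, reports = reports, ages = ages,
       diversity = diversity, capture = capture, paths = paths)
}

strip_for_yaml <- function(x) {
  if (is.list(x)) lapply(x, strip_for_yaml)
  else if (is.numeric(x) || is.character(x) || is.logical(x)) x
  else as.character(x)
}

#' Summary report: per-family table plus global ratios
#'
#' @param reports row-bound [family_report()] table.
#' @param ages [date_copies()] table.
#' @param capture optional [capture_census()] result.
#' @param diversity optional per-family diversity list from [run_all()].
#' @return list: `per_family` data.frame and `ratios` (named percentages;
#'   capture/transcript cells `NA` when those inputs were absent).
#' @export
summary_report <- function(reports, ages, capture = NULL, diversity = NULL) {
  per_family <- reports
  if (!is.null(diversity) && length(diversity)) {
    mod <- stats::setNames(
      vapply(diversity, function(d) d$modality %||% NA_character_,
             character(1)),
      vapply(diversity, `[[`, character(1), "family"))
    per_family$modality <- mod[per_family$family]
  }
  n_copies <- sum(reports$copy_count)
  n_intact <- sum(reports$intact_count)
  ratios <- c(
    intact_pct_of_copies = if (n_copies) ratio_percent(n_intact, n_copies)
                           else NA_real_,
    recent_pct = if (nrow(ages) && any(!is.na(ages$k)))
      ratio_percent(sum(ages$k <= 0.06, na.rm = TRUE), sum(!is.na(ages$k)))
      else NA_real_,
    capture_pct = if (!is.null(capture))
      ratio_percent(sum(capture$per_element$n_fragments >= 1),
                    nrow(capture$per_element)) else NA_real_)
  list(per_family = per_family, ratios = ratios)
}
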