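#' Default characterization configuration
#'
#' All report thresholds live here: motif profile and mismatch allowances,
#' tandem-repeat period/copy bounds, codon-count exclusions, and rounding
#' used for formatted output (raw doubles are always kept alongside).
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    genetic_code = 2L,
    motifs = default_csb_profile(),
    repeat_min_period = 1L,
    repeat_max_period = 10L,
    repeat_min_copies = 2,
    exclude_start_codons = TRUE,
    exclude_stop_codons = TRUE,
    round_pct = 2L,
    round_skew = 4L
  )
}

validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  # the motif profile is a data.frame and must be replaced wholesale,
  # not merged column-wise by modifyList
  motifs <- config$motifs %||% base$motifs
  cfg <- utils::modifyList(base[names(base) != "motifs"],
                           config[names(config) != "motifs"])
  cfg$motifs <- motifs
  stopifnot(cfg$repeat_min_period >= 1L,
            cfg$repeat_max_period >= cfg$repeat_min_period,
            cfg$repeat_min_copies >= 2,
            is.data.frame(cfg$motifs))
  cfg
}

#' Read a characterization configuration from YAML
#'
#' @param path YAML file; keys as in [default_config()] (the motif profile
#'   as a list of name/sequence/max_mismatch records).
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$motifs)) {
    raw$motifs <- do.call(rbind, lapply(raw$motifs, function(m) {
      data.frame(name = m$name, sequence = m$sequence,
                 max_mismatch = as.integer(m$max_mismatch %||% 0L),
                 stringsAsFactors = FALSE)
    }))
  }
  validate_config(raw)
}

run_section <- function(expr) {
  tryCatch(list(status = "ok", result = expr, error = NULL),
           error = function(e) list(status = "failed", result = NULL,
                                    error = conditionMessage(e)))
}

#' Run the full mitogenome characterization pipeline
#'
#' Runs architecture, composition, codon usage, control-region and tRNA
#' analysis in order. Sections run independently: a failing section is
#' recorded with its error while the rest continue, and sequence-dependent
#' sections are marked skipped when only an annotation table (no sequence)
#' is supplied. Output is deterministic for a given input and
#' configuration.
#'
#' @param table A `feature_table`.
#' @param record Optional `genome_record`; NULL for table-only mode.
#' @param config Configuration overrides (see [default_config()]).
#' @return Object of class `characterization_report`: list with
#'   `provenance` and sections `architecture`, `composition`, `codon`,
#'   `control_region`, `trna`, each `list(status, result, error)` where
#'   status is "ok", "failed" or "skipped".
#' @export
characterize <- function(table, record = NULL, config = list()) {
  stopifnot(inherits(table, "feature_table"))
  cfg <- validate_config(config)
  code <- genetic_code(cfg$genetic_code)
  skipped <- list(status = "skipped: no sequence", result = NULL, error = NULL)

  report <- list()
  report$architecture <- run_section(architecture_report(table))

  if (is.null(record)) {
    report$composition <- skipped
    report$codon <- skipped
    report$control_region <- skipped
    report$trna <- skipped
  } else {
    stopifnot(inherits(record, "genome_record"))
    f <- table$features
    report$composition <- run_section({
      per_gene <- lapply(seq_len(nrow(f)), function(i) {
        base_composition(extract_gene_sequence(record, f[i, ]),
                         scope = f$name[i])
      })
      names(per_gene) <- f$name
      list(genome = base_composition(record$sequence, scope = "genome"),
           pcg_concat = pcg_concat_composition(record, table),
           per_gene = per_gene)
    })
    report$codon <- run_section({
      pcg <- f[f$class == "PCG", , drop = FALSE]
      cds <- lapply(seq_len(nrow(pcg)),
                    function(i) extract_gene_sequence(record, pcg[i, ]))
      names(cds) <- pcg$name
      counts <- codon_counts(cds, code,
                             exclude_start = cfg$exclude_start_codons,
                             exclude_stop = cfg$exclude_stop_codons)
      classes <- lapply(cds, function(s) extract_codons(s, code)$classification)
      list(counts = counts, rscu = rscu(counts, code),
           classification = classes,
           total_codons = sum(counts))
    })
    report$control_region <- run_section({
      cr_row <- f[f$class == "CR", , drop = FALSE]
      if (nrow(cr_row) == 0L) stop("no control region annotated")
      cr_seq <- extract_gene_sequence(record, cr_row[1L, ])
      rep <- control_region_report(cr_seq, motifs = cfg$motifs,
                                   min_period = cfg$repeat_min_period,
                                   max_period = cfg$repeat_max_period,
                                   min_copies = cfg$repeat_min_copies)
      ol_row <- f[f$class == "OL", , drop = FALSE]
      if (nrow(ol_row) > 0L) {
        rep$ol_hairpin <- hairpin_check(extract_gene_sequence(record, ol_row[1L, ]))
      }
      rep
    })
    report$trna <- run_section({
      tr <- f[f$class == "tRNA", , drop = FALSE]
      models <- lapply(seq_len(nrow(tr)), function(i) {
        fold_cloverleaf(extract_gene_sequence(record, tr[i, ]))
      })
      names(models) <- tr$name
      list(models = models,
           gu_total = sum(vapply(models, function(m) m$gu_pairs, numeric(1))),
           dhu_less = names(models)[vapply(models, function(m)
             is.null(m$dhu_arm), logical(1))])
    })
  }

  seq_digest <- if (!is.null(record)) {
    tf <- tempfile(); writeLines(record$sequence, tf)
    on.exit(unlink(tf), add = TRUE)
    unname(tools::md5sum(tf))
  } else NA_character_
  report$provenance <- list(
    package_version = as.character(utils::packageVersion("mitochar")),
    genome_id = if (!is.null(record)) record$id else NA_character_,
    genome_length = table$genome_length,
    n_features = nrow(table$features),
    sequence_md5 = seq_digest,
    config = cfg[setdiff(names(cfg), "motifs")],
    motif_profile = cfg$motifs
  )
  structure(report, class = "characterization_report")
}

#' Write a characterization report as JSON
#'
#' Deterministic serialization (no timestamps): the same input and
#' configuration produce byte-identical files.
#'
#' @param report A `characterization_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "characterization_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
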