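#' Pipeline configuration: every stage threshold in one place
#'
#' Defaults are the thresholds of the published screening rules: 5-fold /
#' p < 0.05 / 1 RPKM for organ-high transcripts, 10 RPM for organ-specific
#' small RNAs, 5 RPM organ-mean for the miRNA catalog, 50% same-direction
#' bracket coverage, 15 base pairs minimum stem, 40 base pairs for a "long
#' stem" eligible for phasing, and the degradome rules (5-fold site versus
#' surrounding, top-12 signature rank, 0 nt positional tolerance).
#'
#' @param fold,alpha,floor Organ-high transcript screen thresholds.
#' @param srna_rpm_min Organ-specific small-RNA RPM threshold.
#' @param catalog_min_rpm Catalog accumulation filter (organ-mean RPM).
#' @param min_coverage Bracket-coverage fraction.
#' @param min_stem_pairs,max_gap Stem-loop detection parameters.
#' @param long_stem_pairs Minimum helix pairs for the phasing search.
#' @param phase_min_chain,phase_tol Phased-block chaining parameters.
#' @param deg_fold,deg_top_k,deg_tolerance Degradome validation parameters.
#' @param target_threshold Complementarity-score ceiling of the plumbing
#'   target scanner.
#' @param mir_prefix Candidate identifier prefix.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fold = 5, alpha = 0.05, floor = 1,
                            srna_rpm_min = 10, catalog_min_rpm = 5,
                            min_coverage = 0.5, min_stem_pairs = 15L,
                            max_gap = 12L, long_stem_pairs = 40L,
                            phase_min_chain = 2L, phase_tol = 0L,
                            deg_fold = 5, deg_top_k = 12L,
                            deg_tolerance = 0L, target_threshold = 4,
                            mir_prefix = "can-miR-") {
  cfg <- list(fold = fold, alpha = alpha, floor = floor,
              srna_rpm_min = srna_rpm_min, catalog_min_rpm = catalog_min_rpm,
              min_coverage = min_coverage, min_stem_pairs = min_stem_pairs,
              max_gap = max_gap, long_stem_pairs = long_stem_pairs,
              phase_min_chain = phase_min_chain, phase_tol = phase_tol,
              deg_fold = deg_fold, deg_top_k = deg_top_k,
              deg_tolerance = deg_tolerance,
              target_threshold = target_threshold, mir_prefix = mir_prefix)
  num <- vapply(cfg[setdiff(names(cfg), "mir_prefix")], as.numeric, 0)
  if (any(num[setdiff(names(num), c("phase_tol", "deg_tolerance"))] <= 0)) {
    stop("pipeline thresholds must be positive")
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

.config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full organ-specific regulatory-map pipeline
#'
#' Executes the stages in order on an in-memory input bundle (the shape
#' produced by [simulate_dataset()]): expression screen, small-RNA screen,
#' miRNA catalog, precursor structure screen (bracket coverage, stem-loop,
#' duplex/star calls), phasing on long stems, and degradome analysis
#' (processing evidence, target-site validation, organ-specificity of
#' regulation). When `bundle$deg_libs` is absent the degradome stage is
#' skipped with a warning and the manifest records the skip.
#'
#' @param bundle List with elements `catalog`, `structures`, `srna_libs`,
#'   `expression` (`list(counts, lengths)`), `reference`, optionally
#'   `deg_libs`; plus an [organ_design()] in `bundle$config$design` or passed
#'   via `design`.
#' @param config A [pipeline_config()].
#' @param design Organ design (default taken from `bundle$config$design`).
#' @param out_dir Optional directory: per-stage TSVs, `summary.json` and
#'   `manifest.json` are written there.
#' @return List of class `pipeline_result`: per-stage results, `summary`
#'   (set sizes and funnel counts) and `manifest`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(), design = NULL,
                         out_dir = NULL) {
  if (is.null(design)) design <- bundle$config$design
  stopifnot(inherits(design, "organ_design"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## expression screen
  expr_res <- stage("expression_screen", {
    rpkm <- compute_rpkm(bundle$expression$counts, bundle$expression$lengths)
    list(rpkm = rpkm,
         organ_high = organ_specific_transcripts(
           rpkm, design, fold = config$fold, alpha = config$alpha,
           floor = config$floor))
  })

  ## small-RNA screen
  srna_res <- stage("srna_screen", {
    list(organ_specific = organ_specific_srnas(
           bundle$srna_libs, design, rpm_min = config$srna_rpm_min),
         overlap = library_overlap(bundle$srna_libs, design))
  })

  ## miRNA catalog
  cat_res <- stage("mirna_catalog", {
    full <- match_reference(bundle$reference, bundle$srna_libs, design,
                            prefix = config$mir_prefix)
    list(full = full,
         filtered = expression_filter(full, min_rpm = config$catalog_min_rpm))
  })

  ## precursor structure screen
  prec_res <- stage("precursor_structure", {
    pms <- lapply(bundle$structures, function(s) parse_dot_bracket(s$structure))
    rows <- list()
    duplex_loci <- list()
    for (ci in seq_len(nrow(cat_res$filtered))) {
      mir_id <- cat_res$filtered$id[ci]
      mir_seq <- cat_res$filtered$sequence[ci]
      hits <- map_perfect(mir_seq, bundle$catalog)
      hits <- hits[hits$transcript %in% names(pms), , drop = FALSE]
      for (hi in seq_len(nrow(hits))) {
        tx <- hits$transcript[hi]
        pm <- pms[[tx]]
        cov <- bracket_coverage_screen(pm, hits$start[hi], hits$end[hi],
                                       min_frac = config$min_coverage)
        sl <- if (cov$pass) {
          detect_stem_loop(pm, hits$start[hi], hits$end[hi],
                           min_stem_pairs = config$min_stem_pairs,
                           max_gap = config$max_gap)
        } else NULL
        dc <- if (!is.null(sl) && sl$contains_mir) {
          find_star(pm, hits$start[hi], hits$end[hi],
                    transcript_seq = bundle$catalog[[tx]],
                    libs = bundle$srna_libs)
        } else NULL
        rows[[length(rows) + 1L]] <- data.frame(
          mir_id = mir_id, transcript = tx,
          start = hits$start[hi], end = hits$end[hi],
          coverage = cov$coverage, coverage_pass = cov$pass,
          stem_loop = !is.null(sl) && sl$contains_mir,
          stem_pairs = if (is.null(sl)) NA_integer_ else sl$n_pairs,
          star_start = if (is.null(dc)) NA_integer_ else dc$star[1L],
          star_end = if (is.null(dc)) NA_integer_ else dc$star[2L],
          star_detected = if (is.null(dc)) NA else dc$star_detected,
          stringsAsFactors = FALSE)
        if (!is.null(dc)) {
          duplex_loci[[length(duplex_loci) + 1L]] <- data.frame(
            transcript = tx,
            start = c(hits$start[hi], dc$star[1L]),
            end = c(hits$end[hi], dc$star[2L]),
            label = paste0(mir_id, c("", "*")), stringsAsFactors = FALSE)
        }
      }
    }
    report <- if (length(rows)) do.call(rbind, rows) else data.frame()
    list(report = report,
         duplex_loci = if (length(duplex_loci)) do.call(rbind, duplex_loci)
                       else NULL,
         pms = pms)
  })

  ## phasing on long stems
  phase_res <- stage("phasing", {
    blocks <- list()
    for (tx in names(prec_res$pms)) {
      pm <- prec_res$pms[[tx]]
      # anchor the stem search on the transcript's widest helix: probe from
      # the outermost pair
      first_pair <- which(!is.na(pm$partner))[1L]
      if (is.na(first_pair)) next
      sl <- detect_stem_loop(pm, first_pair, first_pair,
                             min_stem_pairs = config$min_stem_pairs,
                             max_gap = config$max_gap)
      if (is.null(sl) || sl$n_pairs < config$long_stem_pairs) next
      loci <- map_srnas_to_stem(bundle$srna_libs, bundle$catalog[[tx]], sl)
      bl <- find_phased_blocks(loci, pm, bundle$catalog[[tx]],
                               bundle$srna_libs,
                               min_chain = config$phase_min_chain,
                               tol = config$phase_tol)
      for (b in bl) {
        b$transcript <- tx
        blocks[[length(blocks) + 1L]] <- b
      }
    }
    blocks
  })

  ## degradome
  deg_skipped <- is.null(bundle$deg_libs)
  deg_res <- if (deg_skipped) {
    warning("degradome libraries missing: degradome stage skipped")
    NULL
  } else {
    stage("degradome", {
      processing <- if (!is.null(prec_res$duplex_loci)) {
        do.call(rbind, lapply(bundle$deg_libs, function(deg) {
          ev <- processing_evidence(deg, prec_res$duplex_loci,
                                    tolerance = config$deg_tolerance)
          if (nrow(ev)) cbind(organ = deg$organ, ev) else NULL
        }))
      } else NULL
      calls <- list()
      for (ci in seq_len(nrow(cat_res$filtered))) {
        mir_seq <- cat_res$filtered$sequence[ci]
        for (tx in names(bundle$catalog)) {
          sites <- scan_targets(mir_seq, bundle$catalog[[tx]], transcript = tx,
                                threshold = config$target_threshold)
          for (site in sites) {
            cl <- validate_cleavage(site, bundle$deg_libs,
                                    fold = config$deg_fold,
                                    top_k = config$deg_top_k)
            cl$mir_id <- cat_res$filtered$id[ci]
            calls[[length(calls) + 1L]] <- cl
          }
        }
      }
      supported <- Filter(function(cl) cl$supported, calls)
      list(processing = processing, calls = calls, supported = supported,
           specificity = if (length(supported)) {
             organ_specificity_of_regulation(
               supported,
               vegetative = setdiff(design$organs, "flower"))
           } else NULL)
    })
  }

  summary <- list(
    organ_high_transcripts = lapply(expr_res$organ_high, length),
    organ_specific_srnas = lapply(srna_res$organ_specific, length),
    catalog_candidates = nrow(cat_res$full),
    catalog_filtered = nrow(cat_res$filtered),
    precursor_placements = if (nrow(prec_res$report)) nrow(prec_res$report) else 0L,
    coverage_pass = if (nrow(prec_res$report)) sum(prec_res$report$coverage_pass) else 0L,
    stem_loop_pass = if (nrow(prec_res$report)) sum(prec_res$report$stem_loop) else 0L,
    duplex_calls = if (nrow(prec_res$report)) sum(!is.na(prec_res$report$star_start)) else 0L,
    star_detected = if (nrow(prec_res$report)) sum(prec_res$report$star_detected %in% TRUE) else 0L,
    phased_blocks = length(phase_res),
    phased_duplexes = sum(vapply(phase_res, function(b) b$n_duplexes, 0L)),
    degradome_skipped = deg_skipped,
    validated_pairs = if (deg_skipped) NA_integer_ else length(deg_res$supported),
    organ_specific_pairs = if (deg_skipped || is.null(deg_res$specificity)) NA_integer_
                           else sum(deg_res$specificity$organ_specific)
  )

  manifest <- list(
    package = "srnamap",
    version = as.character(utils::packageVersion("srnamap")),
    config = unclass(config),
    config_hash = .config_hash(unclass(config)),
    design = list(organs = design$organs, replicates = design$replicates),
    stages_skipped = if (deg_skipped) "degradome" else character(0)
  )

  result <- structure(list(
    expression = expr_res, srna = srna_res, catalog = cat_res,
    precursor = prec_res, phasing = phase_res, degradome = deg_res,
    summary = summary, manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (nrow(prec_res$report)) {
      write.table(prec_res$report, file.path(out_dir, "precursor_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(cat_res$full, file.path(out_dir, "mirna_catalog.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!deg_skipped && !is.null(deg_res$specificity)) {
      write.table(deg_res$specificity,
                  file.path(out_dir, "regulation_specificity.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("pipeline result\n")
  cat("  organ-high transcripts:",
      paste(sprintf("%s=%d", names(s$organ_high_transcripts),
                    unlist(s$organ_high_transcripts)), collapse = ", "), "\n")
  cat("  organ-specific sRNAs:  ",
      paste(sprintf("%s=%d", names(s$organ_specific_srnas),
                    unlist(s$organ_specific_srnas)), collapse = ", "), "\n")
  cat(sprintf("  catalog: %d candidates, %d above accumulation filter\n",
              s$catalog_candidates, s$catalog_filtered))
  cat(sprintf("  precursor funnel: %d placements -> %d coverage -> %d stem-loop -> %d duplexes (%d star-detected)\n",
              s$precursor_placements, s$coverage_pass, s$stem_loop_pass,
              s$duplex_calls, s$star_detected))
  cat(sprintf("  phasing: %d blocks, %d duplexes\n",
              s$phased_blocks, s$phased_duplexes))
  if (isTRUE(s$degradome_skipped)) {
    cat("  degradome: skipped\n")
  } else {
    cat(sprintf("  degradome: %d validated pairs (%d organ-specific)\n",
                s$validated_pairs, s$organ_specific_pairs))
  }
  invisible(x)
}
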