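#' @importFrom stats rgeom rpois runif
NULL

.rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulation configuration for the synthetic pipeline bundle
#'
#' Defines the study conditions the generator emulates: four organs with two
#' replicates, a 200-transcript expression matrix with organ-high transcripts
#' planted at 8-fold over 5% replicate noise, hairpin precursors carrying
#' planted miRNA/miRNA* duplexes (one profiled organ each), a long-stem
#' hairpin carrying a phased duplex block, organ-specific small RNAs planted
#' at 15 RPM, a broadly shared background small-RNA population, and degradome
#' libraries with processing/cleavage spikes (100 RPM) over a 2-RPM uniform
#' background.
#'
#' @param seed Integer RNG seed; a fixed seed makes every emitted file
#'   byte-identical across runs.
#' @param design An [organ_design()].
#' @param n_transcripts,length_range,n_planted_per_organ,planted_fold,cv,base_mean
#'   Expression-matrix shape: transcript count, length range (nt), planted
#'   organ-high transcripts per organ, their fold, lognormal replicate
#'   coefficient of variation, and baseline mean mapped-read count.
#' @param hairpin List: `arm`, `loop`, `flank`, `mir_offset`, `mir_len`,
#'   `bulges` for the standard precursor hairpins (one per organ).
#' @param phased_k Number of head-to-tail duplexes planted on the long-stem
#'   phased hairpin.
#' @param n_specific_per_organ,specific_rpm Planted organ-specific small RNAs
#'   per organ and their RPM in the planted organ's replicates.
#' @param n_background,background_detect_prob Background small-RNA population
#'   size and per-library detection probability (sRNA populations are heavily
#'   shared between organs; dropout is occasional).
#' @param srna_total Small-RNA library total (reads), padded by a shared
#'   filler sequence.
#' @param degradome List: `spike_rpm`, `background_rpm`, `n_background_tags`,
#'   `total`, `tag_len`.
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              design = organ_design(),
                              n_transcripts = 200L,
                              length_range = c(400L, 2000L),
                              n_planted_per_organ = 5L,
                              planted_fold = 8,
                              cv = 0.05,
                              base_mean = 100,
                              hairpin = list(arm = 60L, loop = 6L, flank = 30L,
                                             mir_offset = 10L, mir_len = 21L,
                                             bulges = 0L),
                              phased_k = 3L,
                              n_specific_per_organ = 3L,
                              specific_rpm = 15,
                              n_background = 300L,
                              background_detect_prob = 0.9,
                              srna_total = 1e6,
                              degradome = list(spike_rpm = 100,
                                               background_rpm = 2,
                                               n_background_tags = 8L,
                                               total = 5e5,
                                               tag_len = 20L)) {
  stopifnot(inherits(design, "organ_design"))
  if (planted_fold <= 1) stop("planted fold must exceed 1")
  if (cv < 0) stop("replicate CV must be non-negative")
  structure(list(seed = as.integer(seed), design = design,
                 n_transcripts = n_transcripts, length_range = length_range,
                 n_planted_per_organ = n_planted_per_organ,
                 planted_fold = planted_fold, cv = cv, base_mean = base_mean,
                 hairpin = hairpin, phased_k = phased_k,
                 n_specific_per_organ = n_specific_per_organ,
                 specific_rpm = specific_rpm,
                 n_background = n_background,
                 background_detect_prob = background_detect_prob,
                 srna_total = srna_total, degradome = degradome),
            class = "sim_config")
}

#' Construct a hairpin precursor transcript with planted miRNA loci
#'
#' Emits the transcript sequence and its dot-bracket structure by
#' construction (no folding): 5' flank, 5' arm, loop, reverse complement of
#' the arm with optional bulge insertions, 3' flank. The mature miRNA sits at
#' the configured offset on the 5' arm; the star locus follows from the 2-nt
#' 3'-overhang duplex geometry.
#'
#' @param arm,loop,flank5,flank3 Segment lengths (nt).
#' @param mir_offset Unpaired-arm nucleotides before the mature locus.
#' @param mir_len Mature miRNA length.
#' @param bulges Number of single-nucleotide bulges inserted into the 3' arm.
#' @return List: `sequence`, `structure` (dot-bracket), `pm` (pairing map),
#'   `mir` and `star` coordinate pairs, `mir_seq`, `star_seq` (star fields
#'   `NULL` when bulges break the duplex geometry).
#' @export
make_hairpin <- function(arm = 60L, loop = 6L, flank5 = 30L, flank3 = 30L,
                         mir_offset = 10L, mir_len = 21L, bulges = 0L) {
  if (mir_offset + mir_len > arm) {
    stop(sprintf("infeasible geometry: arm %d cannot host a %d-nt locus at offset %d",
                 arm, mir_len, mir_offset))
  }
  arm5 <- .rand_seq(arm)
  loop_seq <- .rand_seq(loop)
  arm3_chars <- strsplit(.revcomp(arm5), "")[[1L]]
  db3 <- rep(")", arm)
  if (bulges > 0L) {
    at <- sort(sample(2L:(arm - 1L), bulges))
    for (b in rev(at)) {
      arm3_chars <- append(arm3_chars, sample(c("A", "C", "G", "T"), 1L), after = b)
      db3 <- append(db3, ".", after = b)
    }
  }
  seq <- paste0(.rand_seq(flank5), arm5, loop_seq,
                paste(arm3_chars, collapse = ""), .rand_seq(flank3))
  db <- paste0(strrep(".", flank5), strrep("(", arm), strrep(".", loop),
               paste(db3, collapse = ""), strrep(".", flank3))
  pm <- parse_dot_bracket(db)
  mir <- c(flank5 + mir_offset + 1L, flank5 + mir_offset + mir_len)
  dc <- find_star(pm, mir[1L], mir[2L], transcript_seq = seq)
  list(sequence = seq, structure = db, pm = pm,
       mir = mir, mir_seq = substr(seq, mir[1L], mir[2L]),
       star = if (is.null(dc)) NULL else dc$star,
       star_seq = if (is.null(dc)) NULL else dc$star_seq)
}

.resolve_tag_conflicts <- function(pl) {
  # one tag sequence must carry one count; keep the max observed
  mx <- tapply(pl$count, pl$sequence, max)
  pl$count <- as.numeric(mx[pl$sequence])
  pl
}

#' Generate a complete synthetic analysis bundle with planted ground truth
#'
#' Builds, deterministically from `cfg$seed`: hairpin precursor transcripts
#' (one profiled organ each, plus a long-stem hairpin carrying a planted
#' phased block of `phased_k` duplexes), target transcripts with perfectly
#' complementary miRNA sites, a mature-miRNA reference (with redundant names,
#' undetectable entries and one low-accumulation entry), eight small-RNA
#' libraries, four degradome libraries, and a raw expression count matrix
#' with planted organ-high transcripts.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `sim_bundle`: `catalog` (transcript_catalog),
#'   `structures` (named `list(sequence, structure)` for hairpins),
#'   `srna_libs`, `deg_libs`, `expression = list(counts, lengths)`,
#'   `reference`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  design <- cfg$design
  organs <- design$organs
  hp_cfg <- cfg$hairpin
  mir_len <- hp_cfg$mir_len

  ## --- hairpin precursors, one profiled organ each -----------------------
  hairpins <- list()
  for (i in seq_along(organs)) {
    h <- make_hairpin(arm = hp_cfg$arm, loop = hp_cfg$loop,
                      flank5 = hp_cfg$flank, flank3 = hp_cfg$flank,
                      mir_offset = hp_cfg$mir_offset, mir_len = mir_len,
                      bulges = hp_cfg$bulges)
    h$id <- sprintf("hairpin%02d", i)
    h$organ <- organs[i]
    hairpins[[h$id]] <- h
  }

  ## --- long-stem hairpin with a planted phased block ---------------------
  k <- cfg$phased_k
  chain_offset <- 2L
  phased_arm <- max(40L, chain_offset + k * mir_len + 4L)
  ph <- make_hairpin(arm = phased_arm, loop = hp_cfg$loop,
                     flank5 = hp_cfg$flank, flank3 = hp_cfg$flank,
                     mir_offset = chain_offset, mir_len = mir_len, bulges = 0L)
  ph$id <- "hairpin_phased"
  ph$organ <- organs[[min(2L, length(organs))]]
  chain <- lapply(seq_len(k), function(i) {
    s <- hp_cfg$flank + chain_offset + (i - 1L) * mir_len + 1L
    c(s, s + mir_len - 1L)
  })
  chain_seqs <- vapply(chain, function(lc) substr(ph$sequence, lc[1L], lc[2L]), "")
  partners <- lapply(chain, function(lc) {
    dc <- find_star(ph$pm, lc[1L], lc[2L], transcript_seq = ph$sequence)
    list(locus = dc$star, seq = dc$star_seq)
  })
  ph$chain <- chain
  ph$chain_seqs <- chain_seqs
  ph$partners <- partners
  hairpins[[ph$id]] <- ph

  hp_seqs <- vapply(hairpins, `[[`, "", "sequence")

  ## --- target transcripts: one perfectly complementary site per hairpin miR
  targets <- list()
  for (h in hairpins[seq_along(organs)]) {
    tlen <- 600L
    w <- 301L
    site_seq <- .revcomp(h$mir_seq)
    tx <- paste0(.rand_seq(w - 1L), site_seq,
                 .rand_seq(tlen - w - mir_len + 1L))
    id <- paste0("target_", h$id)
    targets[[id]] <- list(id = id, sequence = tx, mir_id = h$id,
                          mir_seq = h$mir_seq,
                          window = c(w, w + mir_len - 1L),
                          cleavage_pos = w + mir_len - 10L,
                          organ = h$organ)
  }
  target_seqs <- vapply(targets, `[[`, "", "sequence")

  all_tx <- c(hp_seqs, target_seqs)
  catalog <- transcript_catalog(all_tx)
  haystack <- paste(all_tx, collapse = "#")
  fresh_seq <- function(len, taken) {
    repeat {
      s <- .rand_seq(len)
      if (!grepl(s, haystack, fixed = TRUE) && !(s %in% taken)) return(s)
    }
  }

  ## --- planted organ-specific sRNAs and shared background ----------------
  planted_seqs <- c(vapply(hairpins, `[[`, "", "mir_seq"),
                    vapply(hairpins, function(h) {
                      if (is.null(h$star_seq)) "" else h$star_seq
                    }, ""),
                    chain_seqs,
                    vapply(partners, function(p) p$seq, ""))
  planted_seqs <- planted_seqs[nzchar(planted_seqs)]

  specific <- lapply(organs, function(o) {
    vapply(seq_len(cfg$n_specific_per_organ), function(i) {
      s <- fresh_seq(21L, planted_seqs)
      planted_seqs <<- c(planted_seqs, s)
      s
    }, "")
  })
  names(specific) <- organs

  background <- vapply(seq_len(cfg$n_background), function(i) {
    s <- fresh_seq(21L, planted_seqs)
    planted_seqs <<- c(planted_seqs, s)
    s
  }, "")

  low_rpm_seq <- fresh_seq(21L, planted_seqs)
  planted_seqs <- c(planted_seqs, low_rpm_seq)
  filler <- fresh_seq(30L, planted_seqs)

  ## --- mature miRNA reference -------------------------------------------
  reference <- character(0)
  for (i in seq_along(organs)) {
    h <- hairpins[[i]]
    reference[sprintf("sp1-miR%03d", i)] <- h$mir_seq
    reference[sprintf("sp2-miR%03d", i)] <- h$mir_seq # redundant entry
    if (!is.null(h$star_seq)) {
      reference[sprintf("sp1-miR%03d*", i)] <- h$star_seq
    }
  }
  reference[paste0("sp3-miR-absent", seq_len(5L))] <-
    vapply(seq_len(5L), function(i) fresh_seq(21L, planted_seqs), "")
  reference["sp3-miR-low"] <- low_rpm_seq

  ## --- small-RNA libraries ----------------------------------------------
  spike <- function(organ_match, hi, lo) if (organ_match) hi else lo
  srna_libs <- list()
  for (o in organs) for (r in seq_len(design$replicates)) {
    counts <- numeric(0)
    for (h in hairpins) {
      is_o <- identical(h$organ, o)
      counts[h$mir_seq] <- rpois(1L, spike(is_o, 2000, 40))
      if (!is.null(h$star_seq)) {
        counts[h$star_seq] <- rpois(1L, spike(is_o, 800, 20))
      }
    }
    ph_is_o <- identical(ph$organ, o)
    for (i in seq_len(k)) {
      counts[ph$chain_seqs[i]] <- rpois(1L, spike(ph_is_o, 500, 30))
      counts[ph$partners[[i]]$seq] <- rpois(1L, spike(ph_is_o, 300, 15))
    }
    counts[counts == 0] <- 1 # planted sequences are detected everywhere
    for (s in specific[[o]]) {
      counts[s] <- ceiling(cfg$specific_rpm * cfg$srna_total / 1e6)
    }
    present <- runif(cfg$n_background) < cfg$background_detect_prob
    bg_counts <- 1 + rgeom(cfg$n_background, 0.3)
    counts[background[present]] <- bg_counts[present]
    counts[low_rpm_seq] <- 4
    counts[filler] <- cfg$srna_total - sum(counts)
    srna_libs[[paste(o, r, sep = "_")]] <-
      srna_library(counts, organ = o, replicate = as.character(r))
  }

  ## --- degradome libraries ----------------------------------------------
  dg <- cfg$degradome
  spike_count <- max(1, round(dg$spike_rpm * dg$total / 1e6))
  bg_count <- max(1, round(dg$background_rpm * dg$total / 1e6))
  tag_at <- function(seq, pos) substr(seq, pos, pos + dg$tag_len - 1L)
  deg_libs <- list()
  processing_truth <- list()
  for (o in organs) {
    rows <- list()
    add <- function(tx_id, tx_seq, pos, count) {
      if (pos < 1L || pos + dg$tag_len - 1L > nchar(tx_seq)) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        transcript = tx_id, pos = pos, sequence = tag_at(tx_seq, pos),
        count = count, stringsAsFactors = FALSE)
    }
    for (h in hairpins) {
      if (identical(h$organ, o)) {
        # processing spikes at the duplex ends
        add(h$id, h$sequence, h$mir[1L], spike_count)
        add(h$id, h$sequence, h$mir[2L] + 1L, spike_count)
        if (!is.null(h$star)) add(h$id, h$sequence, h$star[2L] + 1L, spike_count)
        if (!is.null(h$chain)) {
          for (lc in h$chain) add(h$id, h$sequence, lc[2L] + 1L, spike_count)
        }
        processing_truth[[length(processing_truth) + 1L]] <-
          list(transcript = h$id, organ = o)
      }
      # sparse background on the precursor
      for (p in sample(seq_len(nchar(h$sequence) - dg$tag_len), 2L)) {
        add(h$id, h$sequence, p, bg_count)
      }
    }
    for (tg in targets) {
      avoid <- c(tg$cleavage_pos, tg$cleavage_pos - 1L)
      cand <- setdiff(seq_len(nchar(tg$sequence) - dg$tag_len), avoid)
      for (p in sample(cand, dg$n_background_tags)) {
        add(tg$id, tg$sequence, p, bg_count)
      }
      if (identical(tg$organ, o)) {
        add(tg$id, tg$sequence, tg$cleavage_pos, spike_count)
      }
    }
    pl <- .resolve_tag_conflicts(do.call(rbind, rows))
    deg_libs[[o]] <- degradome_library(pl, organ = o, total = dg$total)
  }

  ## --- expression matrix -------------------------------------------------
  tx_ids <- sprintf("tx%03d", seq_len(cfg$n_transcripts))
  lengths <- setNames(
    sample(seq(cfg$length_range[1L], cfg$length_range[2L]),
           cfg$n_transcripts, replace = TRUE), tx_ids)
  planted_tx <- split(
    tx_ids[seq_len(cfg$n_planted_per_organ * length(organs))],
    rep(organs, each = cfg$n_planted_per_organ))
  planted_tx <- planted_tx[organs]
  sdlog <- sqrt(log(1 + cfg$cv^2))
  samples <- sample_ids(design)
  counts_mat <- matrix(0, cfg$n_transcripts, length(samples),
                       dimnames = list(tx_ids, samples))
  organ_of_sample <- rep(organs, each = design$replicates)
  for (j in seq_along(samples)) {
    mu <- rep(cfg$base_mean, cfg$n_transcripts)
    idx <- match(planted_tx[[organ_of_sample[j]]], tx_ids)
    mu[idx] <- cfg$base_mean * cfg$planted_fold
    counts_mat[, j] <- round(mu * rlnorm(cfg$n_transcripts,
                                         meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }

  truth <- list(
    planted_transcripts = planted_tx,
    specific_srnas = specific,
    hairpins = lapply(hairpins, function(h) {
      h[c("id", "organ", "mir", "mir_seq", "star", "star_seq")]
    }),
    phased = list(transcript = ph$id, organ = ph$organ, k = k,
                  chain = ph$chain, chain_seqs = ph$chain_seqs,
                  partner_loci = lapply(ph$partners, `[[`, "locus"),
                  partner_seqs = vapply(ph$partners, `[[`, "", "seq")),
    targets = lapply(targets, function(tg) {
      tg[c("id", "mir_id", "mir_seq", "window", "cleavage_pos", "organ")]
    }),
    processing = processing_truth,
    low_rpm_seq = low_rpm_seq,
    filler = filler,
    background = background
  )

  structure(list(
    catalog = catalog,
    structures = lapply(hairpins, function(h) {
      list(sequence = h$sequence, structure = h$structure)
    }),
    srna_libs = srna_libs,
    deg_libs = deg_libs,
    expression = list(counts = counts_mat, lengths = lengths),
    reference = reference,
    truth = truth,
    config = cfg
  ), class = "sim_bundle")
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' Emits `transcripts.fasta`, `structures.vienna`, one
#' `srna_<organ>_<rep>.tsv` per library (sequence, count), one
#' `degradome_<organ>.tsv` per organ, `expression_counts.tsv`,
#' `lengths.tsv`, `reference.fasta` and `truth.json`. Output is
#' byte-deterministic for a fixed simulation seed.
#'
#' @param bundle A [simulate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$catalog, file.path(dir, "transcripts.fasta"))
  write_vienna(bundle$structures, file.path(dir, "structures.vienna"))
  for (key in names(bundle$srna_libs)) {
    lib <- bundle$srna_libs[[key]]
    ord <- order(names(lib$counts))
    write.table(
      data.frame(sequence = names(lib$counts)[ord],
                 count = unname(lib$counts)[ord]),
      file.path(dir, paste0("srna_", key, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  for (o in names(bundle$deg_libs)) {
    write_degradome(bundle$deg_libs[[o]],
                    file.path(dir, paste0("degradome_", o, ".tsv")))
  }
  write_count_matrix(bundle$expression$counts,
                     file.path(dir, "expression_counts.tsv"))
  write.table(data.frame(transcript = names(bundle$expression$lengths),
                         length = unname(bundle$expression$lengths)),
              file.path(dir, "lengths.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(bundle$reference, file.path(dir, "reference.fasta"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
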