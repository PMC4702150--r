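# Shared fixtures built in code. Perfect hairpins are constructed by string
# arithmetic here, independently of the package's own generator, so the
# structure-stage tests check the parser/geometry against a partner table
# derived by a closed-form position formula.

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1L]]), collapse = "")
}

# a perfect hairpin: flank5 . arm ( loop . revcomp(arm) ) flank3 .
perfect_hairpin <- function(arm, loop, flank5 = 0L, flank3 = 0L) {
  arm5 <- rand_nt(arm)
  seq <- paste0(rand_nt(flank5), arm5, rand_nt(loop), revcomp_chr(arm5),
                rand_nt(flank3))
  db <- paste0(strrep(".", flank5), strrep("(", arm), strrep(".", loop),
               strrep(")", arm), strrep(".", flank3))
  # closed-form partner of a 5'-arm position i: mirrored across the loop
  partner_formula <- function(i) 2L * flank5 + 2L * arm + loop - i + 1L
  list(sequence = seq, structure = db, arm = arm, loop = loop,
       flank5 = flank5, flank3 = flank3, partner_formula = partner_formula)
}

# minimal four-organ design and a set of libraries holding given counts in
# every library (counts can be overridden per sample key "organ_rep")
four_organ_design <- function() organ_design()

make_libs <- function(base_counts, overrides = list(), total = NULL,
                      design = four_organ_design()) {
  out <- list()
  for (key in sample_ids(design)) {
    cnt <- base_counts
    if (!is.null(overrides[[key]])) {
      cnt <- overrides[[key]]
    }
    parts <- strsplit(key, "_")[[1L]]
    out[[key]] <- srna_library(cnt, organ = parts[1L], replicate = parts[2L],
                               total = total)
  }
  out
}

# an RPKM-like matrix with per-organ replicate values supplied row-wise:
# values = list(tx_id = c(root1, root2, stem1, stem2, leaf1, leaf2, fl1, fl2))
make_rpkm <- function(values, design = four_organ_design()) {
  m <- do.call(rbind, values)
  dimnames(m) <- list(names(values), sample_ids(design))
  m
}

# a random 21-nt sequence guaranteed absent from a set of sequences
fresh_21mer <- function(avoid = character()) {
  repeat {
    s <- rand_nt(21L)
    if (!any(vapply(avoid, function(a) grepl(s, a, fixed = TRUE), TRUE))) {
      return(s)
    }
  }
}
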