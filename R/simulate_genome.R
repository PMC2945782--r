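# Seeded genome simulator: chromosomes with promoter slots, planted motif
# occurrences at elevated foreground rates, and block-structured
# conservation so that conserved windows exist genome-wide, not only at
# planted sites (masking must not leak the ground truth).

#' Simulate a genome with planted motif occurrences
#'
#' Lays out one promoter slot of `upstream + downstream` bp per gene along
#' a few chromosomes (spacer-separated, never overlapping), with strands
#' drawn 50/50. Background sequence is i.i.d. over `{A, C, G, T}` with
#' configurable base frequencies. A fraction `foreground_rate` of
#' foreground promoters and `background_rate` of background promoters
#' receive one motif instance sampled from the planted PWM's column
#' distributions, inserted at a uniformly drawn offset in promoter
#' orientation.
#'
#' Conservation is block-structured, mimicking the patchy layout of
#' phastCons-style tracks: each promoter is segmented into
#' `cons_block_len`-bp blocks, a block is conserved with probability
#' `cons_block_prob` (per-base values from
#' `Beta(cons_hi_shape[1], cons_hi_shape[2])`, concentrated near 1) and
#' non-conserved otherwise (`Beta(cons_lo_shape[1], cons_lo_shape[2])`,
#' concentrated near 0). Planted-occurrence bases get
#' `conservation_at_plant`. The block structure ensures that
#' conservation-eligible windows occur throughout the universe, so
#' masking does not by itself reveal where sites were planted.
#'
#' @param n_foreground,n_background number of foreground / background
#'   promoters (`n_foreground` must be positive).
#' @param planted_pwm a [pwm] object to plant.
#' @param foreground_rate,background_rate planting probabilities in
#'   `[0, 1]`.
#' @param conservation_at_plant conservation value given to every base of
#'   a planted occurrence.
#' @param upstream,downstream promoter slot extent around the TSS, in bp.
#' @param base_freqs background base frequencies (A, C, G, T).
#' @param cons_block_len conservation block length in bp.
#' @param cons_block_prob probability that a block is conserved.
#' @param cons_hi_shape,cons_lo_shape Beta shape pairs for conserved and
#'   non-conserved blocks.
#' @param n_chroms number of chromosomes genes are distributed over.
#' @param spacer gap in bp between adjacent promoter slots.
#' @param foreground_ids,background_ids optional gene id vectors.
#' @param seed integer seed.
#' @return a list of class `genome_sim`: `genome`
#'   ([Biostrings::DNAStringSet]), `tss` (width-1
#'   [GenomicRanges::GRanges] with `name` and `score`), `conservation`
#'   (per-base [GenomicRanges::GRanges] with `score`), `truth`
#'   (data.frame: `gene_id`, `is_foreground`, `strand`, `has_motif`,
#'   `site_offset` 0-based in promoter orientation, `site_seq`), and the
#'   generator parameters.
#' @export
simulate_genome <- function(n_foreground, n_background, planted_pwm,
                            foreground_rate = 0.4, background_rate = 0.05,
                            conservation_at_plant = 0.95,
                            upstream = 400L, downstream = 100L,
                            base_freqs = rep(0.25, 4),
                            cons_block_len = 50L, cons_block_prob = 0.35,
                            cons_hi_shape = c(24, 1),
                            cons_lo_shape = c(1, 6),
                            n_chroms = 4L, spacer = 50L,
                            foreground_ids = NULL, background_ids = NULL,
                            seed = 1L) {
  if (n_foreground <= 0L) stop("n_foreground must be positive")
  if (n_background < 0L) stop("n_background must be non-negative")
  if (foreground_rate < 0 || foreground_rate > 1 ||
      background_rate < 0 || background_rate > 1) {
    stop("rates must be in [0, 1]")
  }
  stopifnot(inherits(planted_pwm, "pwm"))
  L <- as.integer(upstream + downstream)
  w <- pwm_width(planted_pwm)
  if (w > L) stop("motif wider than promoter")
  stopifnot(length(base_freqs) == 4L, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-6,
            conservation_at_plant >= 0, conservation_at_plant <= 1)

  n <- n_foreground + n_background
  ids <- c(
    foreground_ids %||% sprintf("fg%05d", seq_len(n_foreground)),
    background_ids %||% sprintf("bg%05d", seq_len(n_background))
  )
  stopifnot(length(ids) == n, !anyDuplicated(ids))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  chrom_of <- rep(sprintf("chr%d", seq_len(n_chroms)), length.out = n)
  slot_idx <- stats::ave(seq_len(n), chrom_of, FUN = seq_along)
  slot_start0 <- (slot_idx - 1L) * (L + spacer) + spacer  # 0-based
  strand <- sample(c("+", "-"), n, replace = TRUE)
  is_fg <- c(rep(TRUE, n_foreground), rep(FALSE, n_background))
  plant <- rbinom(n, 1L, ifelse(is_fg, foreground_rate,
                                background_rate)) == 1L
  offset <- ifelse(plant, floor(runif(n, 0, L - w + 1)), NA_integer_)

  # per-chromosome background sequence
  chrom_len <- vapply(split(slot_start0, chrom_of), function(s) {
    max(s) + L + spacer
  }, numeric(1))
  chrom_names <- sort(unique(chrom_of))
  chrom_len <- chrom_len[chrom_names]
  seqs <- lapply(chrom_len, function(len) {
    sample(BASES, len, replace = TRUE, prob = base_freqs)
  })

  # sample one site per planted promoter from the PWM column distributions
  freq <- sweep(planted_pwm$counts, 2, colSums(planted_pwm$counts), "/")
  sample_site <- function() {
    vapply(seq_len(w), function(j) sample(BASES, 1L, prob = freq[, j]), "")
  }
  site_seq <- rep(NA_character_, n)
  cons_list <- vector("list", n)
  n_blocks <- ceiling(L / cons_block_len)
  block_of <- rep(seq_len(n_blocks), each = cons_block_len)[seq_len(L)]
  for (i in seq_len(n)) {
    hi <- rbinom(n_blocks, 1L, cons_block_prob) == 1L
    v <- numeric(L)
    is_hi <- hi[block_of]
    v[is_hi] <- rbeta(sum(is_hi), cons_hi_shape[1], cons_hi_shape[2])
    v[!is_hi] <- rbeta(sum(!is_hi), cons_lo_shape[1], cons_lo_shape[2])
    v <- round(v, 3)
    if (plant[i]) {
      site <- sample_site()
      site_seq[i] <- paste(site, collapse = "")
      o <- offset[i]
      # genomic placement of the promoter-oriented occurrence
      if (strand[i] == "+") {
        gpos <- slot_start0[i] + o + seq_len(w)  # 1-based genomic
        seqs[[chrom_of[i]]][gpos] <- site
      } else {
        gpos <- slot_start0[i] + L - o - w + seq_len(w)
        seqs[[chrom_of[i]]][gpos] <- rev(chartr("ACGT", "TGCA", site))
      }
      v[o + seq_len(w)] <- conservation_at_plant
    }
    cons_list[[i]] <- v
  }

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- chrom_names

  # TSS (0-based position): + strand at slot_start + upstream;
  # - strand at slot_start + downstream - 1, so that the strand-aware
  # window [TSS - upstream, TSS + downstream) covers exactly the slot.
  tss0 <- ifelse(strand == "+", slot_start0 + upstream,
                 slot_start0 + downstream - 1L)
  tss <- GenomicRanges::GRanges(
    chrom_of, IRanges::IRanges(tss0 + 1L, tss0 + 1L), strand = strand,
    name = ids, score = 0L
  )

  # per-base conservation intervals in genomic orientation
  cons_val <- unlist(lapply(seq_len(n), function(i) {
    if (strand[i] == "+") cons_list[[i]] else rev(cons_list[[i]])
  }))
  cons_start0 <- unlist(lapply(seq_len(n), function(i) {
    slot_start0[i] + 0:(L - 1L)
  }))
  cons_chrom <- rep(chrom_of, each = L)
  conservation <- GenomicRanges::GRanges(
    cons_chrom, IRanges::IRanges(cons_start0 + 1L, cons_start0 + 1L),
    score = cons_val
  )

  truth <- data.frame(
    gene_id = ids, is_foreground = is_fg, chrom = chrom_of,
    strand = strand, tss = tss0, has_motif = plant,
    site_offset = ifelse(plant, offset, NA_integer_),
    site_seq = site_seq, stringsAsFactors = FALSE
  )
  structure(list(genome = genome, tss = tss, conservation = conservation,
                 truth = truth, planted_pwm = planted_pwm,
                 upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 seed = as.integer(seed)),
            class = "genome_sim")
}

#' Write a simulated genome as FASTA + BED6 + bedGraph + truth TSV
#'
#' Emits `genome.fa` (60-column wrapped), `tss.bed` (BED6, 0-based
#' half-open), `conservation.bedGraph` (per-base 0-based half-open
#' intervals) and `genome_truth.tsv`.
#'
#' @param sim a `genome_sim` from [simulate_genome()].
#' @param dir output directory.
#' @param header optional comment line for the truth TSV.
#' @return `dir`, invisibly.
#' @export
write_genome_files <- function(sim, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"),
                              width = 60L)
  bed <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(sim$tss)),
    start = BiocGenerics::start(sim$tss) - 1L,
    end = BiocGenerics::start(sim$tss),
    name = sim$tss$name, score = 0L,
    strand = as.character(BiocGenerics::strand(sim$tss))
  )
  data.table::fwrite(bed, file.path(dir, "tss.bed"), sep = "\t",
                     col.names = FALSE)
  bg <- data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(sim$conservation)),
    start = BiocGenerics::start(sim$conservation) - 1L,
    end = BiocGenerics::end(sim$conservation),
    score = sim$conservation$score
  )
  data.table::fwrite(bg, file.path(dir, "conservation.bedGraph"),
                     sep = "\t", col.names = FALSE)
  write_tsv(sim$truth, file.path(dir, "genome_truth.tsv"), header = header)
  invisible(dir)
}
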