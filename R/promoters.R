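# Promoter universe construction: strand-aware TSS windows with aligned
# per-base conservation, and overlap deduplication.

#' Construct a promoter set
#'
#' @param meta data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open genomic interval), `strand`.
#' @param seqs a [Biostrings::DNAStringSet] named by `gene_id`, sequences
#'   in 5'->3' promoter orientation (minus-strand promoters are the
#'   reverse complement of the genomic slice).
#' @param cons a named list of numeric per-base conservation vectors in
#'   `[0, 1]`, aligned to the sequence orientation.
#' @return an object of class `promoter_set`.
#' @export
promoter_set <- function(meta, seqs, cons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(meta)),
            !anyDuplicated(meta$gene_id),
            identical(names(seqs), meta$gene_id),
            identical(names(cons), meta$gene_id))
  widths <- meta$end - meta$start
  if (!all(Biostrings::width(seqs) == widths) ||
      !all(lengths(cons) == widths)) {
    stop("sequence and conservation lengths must equal interval lengths")
  }
  structure(list(meta = meta, seqs = seqs, cons = cons),
            class = "promoter_set")
}

#' @export
length.promoter_set <- function(x) nrow(x$meta)

#' @export
`[.promoter_set` <- function(x, i) {
  promoter_set(x$meta[i, , drop = FALSE], x$seqs[i], x$cons[i])
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set with %d promoters on %d chromosome(s)\n",
              length(x), length(unique(x$meta$chrom))))
  invisible(x)
}

# GRanges view of the genomic intervals (1-based closed, per GRanges).
promoter_granges <- function(x) {
  GenomicRanges::GRanges(
    x$meta$chrom,
    IRanges::IRanges(x$meta$start + 1L, x$meta$end),
    strand = x$meta$strand
  )
}

#' Extract strand-aware promoter windows around TSSs
#'
#' For a plus-strand TSS at 0-based position `t` the window is the genomic
#' interval `[t - upstream, t + downstream)`; for a minus-strand TSS it is
#' `[t - downstream + 1, t + upstream + 1)` and the sequence is
#' reverse-complemented, so that both read 5'->3' with the TSS base as the
#' first downstream base. Windows are clipped to chromosome bounds. Bases
#' with no conservation record get conservation 0.
#'
#' @param tss TSS records: a BED6 file path or a
#'   [GenomicRanges::GRanges] of width-1 ranges with a `name` column.
#' @param genome a FASTA file path or a named
#'   [Biostrings::DNAStringSet] of chromosome sequences.
#' @param conservation a bedGraph file path, a
#'   [GenomicRanges::GRanges] with a `score` column, or `NULL` (all
#'   zero).
#' @param upstream,downstream window extent in bp (defaults 2000 / 1000).
#' @return a [promoter_set].
#' @export
extract_promoter_windows <- function(tss, genome, conservation = NULL,
                                     upstream = 2000L, downstream = 1000L) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("[ \t].*", "", names(genome))
  }
  if (is.character(tss)) tss <- rtracklayer::import(tss, format = "BED")
  stopifnot(methods::is(tss, "GRanges"))
  if (any(!as.character(GenomeInfoDb::seqnames(tss)) %in% names(genome))) {
    stop("chromosome absent from FASTA")
  }
  st <- as.character(BiocGenerics::strand(tss))
  if (any(!st %in% c("+", "-"))) stop("TSS strand must be + or -")
  ids <- tss$name
  if (is.null(ids)) ids <- sprintf("tss%05d", seq_along(tss))

  sl <- setNames(Biostrings::width(genome), names(genome))
  GenomeInfoDb::seqlevels(tss) <- names(genome)
  GenomeInfoDb::seqlengths(tss) <- sl
  win <- suppressWarnings(
    GenomicRanges::trim(GenomicRanges::promoters(
      tss, upstream = upstream, downstream = downstream))
  )

  chrom <- as.character(GenomeInfoDb::seqnames(win))
  start1 <- BiocGenerics::start(win)
  end1 <- BiocGenerics::end(win)

  cons_vec <- NULL
  if (!is.null(conservation)) {
    if (is.character(conservation)) {
      conservation <- read_bedgraph(conservation)
    }
    cons_cov <- GenomicRanges::coverage(conservation,
                                        weight = conservation$score)
    # decode each chromosome once; round away the 1-ulp drift coverage()
    # introduces so threshold comparisons at exact track values (e.g.
    # 0.7 vs >= 0.7) stay stable
    cons_vec <- lapply(cons_cov, function(r) round(as.numeric(r), 6))
  }

  seqs <- vector("list", length(win))
  cons <- vector("list", length(win))
  for (i in seq_along(win)) {
    s <- Biostrings::subseq(genome[[chrom[i]]], start1[i], end1[i])
    v <- numeric(end1[i] - start1[i] + 1L)
    if (!is.null(cons_vec) && chrom[i] %in% names(cons_vec)) {
      seg <- cons_vec[[chrom[i]]]
      hi <- min(end1[i], length(seg))
      if (hi >= start1[i]) {
        v[seq_len(hi - start1[i] + 1L)] <- seg[start1[i]:hi]
      }
    }
    if (st[i] == "-") {
      s <- Biostrings::reverseComplement(s)
      v <- rev(v)
    }
    seqs[[i]] <- s
    cons[[i]] <- v
  }
  seqs <- Biostrings::DNAStringSet(seqs)
  names(seqs) <- ids
  names(cons) <- ids
  promoter_set(
    meta = data.frame(gene_id = ids, chrom = chrom, start = start1 - 1L,
                      end = end1, strand = st, stringsAsFactors = FALSE),
    seqs = seqs, cons = cons
  )
}

#' Deduplicate promoters overlapping by more than a span
#'
#' Overlap is measured on genomic intervals irrespective of strand.
#' While any retained pair overlaps by *more than* `max_overlap` bp
#' (strict inequality: an exactly-`max_overlap` overlap is allowed), the
#' first violating pair in (chrom, start) order is found and one member is
#' discarded uniformly at random under the given seed. A final
#' deterministic restoration pass re-adds (in sorted order) any discarded
#' promoter that no longer conflicts, so the retained set is maximal.
#'
#' @param promoters a [promoter_set].
#' @param seed integer seed for the uniform discards.
#' @param max_overlap maximum allowed pairwise overlap in bp (default
#'   1500).
#' @return the retained [promoter_set], with the discarded gene ids in
#'   attribute `"removed"`.
#' @export
dedupe_overlapping <- function(promoters, seed = 1L, max_overlap = 1500L) {
  n <- length(promoters)
  if (n == 0L) return(promoters)
  ord <- order(promoters$meta$chrom, promoters$meta$start,
               promoters$meta$gene_id)
  promoters <- promoters[ord]
  gr <- promoter_granges(promoters)

  violating_pairs <- function(active) {
    sub <- gr[active]
    h <- GenomicRanges::findOverlaps(sub, minoverlap = max_overlap + 1L,
                                     drop.self = TRUE,
                                     drop.redundant = TRUE,
                                     ignore.strand = TRUE)
    cbind(active[S4Vectors::queryHits(h)], active[S4Vectors::subjectHits(h)])
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  active <- seq_len(n)
  removed <- integer(0)
  repeat {
    pairs <- violating_pairs(active)
    if (nrow(pairs) == 0L) break
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    pair <- pairs[1L, ]
    drop <- pair[sample.int(2L, 1L)]
    active <- setdiff(active, drop)
    removed <- c(removed, drop)
  }
  # restoration pass: maximality
  for (r in sort(removed)) {
    ov <- GenomicRanges::findOverlaps(gr[r], gr[active],
                                      minoverlap = max_overlap + 1L,
                                      ignore.strand = TRUE)
    if (length(ov) == 0L) {
      active <- sort(c(active, r))
      removed <- setdiff(removed, r)
    }
  }
  out <- promoters[sort(active)]
  attr(out, "removed") <- promoters$meta$gene_id[sort(removed)]
  out
}

#' Write a promoter set as FASTA plus per-base conservation TSV
#'
#' FASTA ids follow `gene|chrom:start-end(strand)`; conservation goes to a
#' long-format TSV (`gene_id`, `offset`, `conservation`) with 0-based
#' offsets in promoter orientation.
#'
#' @param x a [promoter_set].
#' @param dir output directory (created if needed).
#' @param header optional comment line prepended to the TSV.
#' @return `dir`, invisibly.
#' @export
write_promoters <- function(x, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- x$seqs
  names(seqs) <- sprintf("%s|%s:%d-%d(%s)", x$meta$gene_id, x$meta$chrom,
                         x$meta$start, x$meta$end, x$meta$strand)
  Biostrings::writeXStringSet(seqs, file.path(dir, "promoters.fa"),
                              width = 60L)
  cons <- data.table::data.table(
    gene_id = rep(x$meta$gene_id, lengths(x$cons)),
    offset = unlist(lapply(x$cons, function(v) seq_along(v) - 1L)),
    conservation = unlist(x$cons)
  )
  path <- file.path(dir, "conservation.tsv")
  if (!is.null(header)) writeLines(header, path)
  data.table::fwrite(cons, path, sep = "\t", append = !is.null(header),
                     col.names = TRUE)
  invisible(dir)
}

#' Read a promoter set written by [write_promoters()]
#'
#' @param dir directory containing `promoters.fa` and `conservation.tsv`.
#' @return a [promoter_set].
#' @export
read_promoters <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "promoters.fa"))
  m <- regmatches(names(seqs),
                  regexec("^([^|]+)\\|([^:]+):(\\d+)-(\\d+)\\(([+-])\\)",
                          names(seqs)))
  if (any(lengths(m) != 6L)) stop("malformed promoter FASTA ids")
  meta <- data.frame(
    gene_id = vapply(m, `[`, "", 2L), chrom = vapply(m, `[`, "", 3L),
    start = as.integer(vapply(m, `[`, "", 4L)),
    end = as.integer(vapply(m, `[`, "", 5L)),
    strand = vapply(m, `[`, "", 6L), stringsAsFactors = FALSE
  )
  names(seqs) <- meta$gene_id
  ct <- data.table::fread(file.path(dir, "conservation.tsv"), sep = "\t",
                          skip = "gene_id")
  cons <- split(ct$conservation, factor(ct$gene_id, levels = meta$gene_id))
  cons <- lapply(cons, as.numeric)
  promoter_set(meta, seqs, cons)
}

#' Read a bedGraph file as a GRanges with a score column
#'
#' @param path bedGraph file (0-based half-open intervals).
#' @return a [GenomicRanges::GRanges] with numeric `score`.
#' @export
read_bedgraph <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (grepl("^(track|#)", first)) 1L else 0L
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "score"),
                          skip = skip)
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(dt$start + 1L, dt$end),
                         score = as.numeric(dt$score))
}
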