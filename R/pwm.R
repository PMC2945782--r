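# Position weight matrices: JASPAR / TRANSFAC text parsing, log-odds
# construction, and synthetic motif generators.

BASES <- c("A", "C", "G", "T")

#' Construct a PWM object
#'
#' @param counts a 4 x width non-negative matrix, rows A, C, G, T.
#' @param motif_id motif identifier.
#' @param source source label (e.g. `"jaspar"`, `"transfac"`,
#'   `"synthetic"`).
#' @param background base frequencies (A, C, G, T), strictly positive,
#'   summing to 1.
#' @param pseudocount non-negative smoothing constant added to every cell
#'   before log-odds conversion (default 0.25).
#' @return an object of class `pwm`.
#' @export
pwm <- function(counts, motif_id, source = "synthetic",
                background = rep(0.25, 4), pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (ncol(counts) < 1L) stop("width must be >= 1")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and finite")
  }
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-6, pseudocount >= 0)
  rownames(counts) <- BASES
  structure(list(motif_id = motif_id, source = source, counts = counts,
                 background = setNames(as.numeric(background), BASES),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s), width %d\n", x$motif_id, x$source,
              ncol(x$counts)))
  print(round(x$counts, 2))
  invisible(x)
}

#' Width of a PWM
#' @param x a [pwm] object.
#' @return integer motif width.
#' @export
pwm_width <- function(x) ncol(x$counts)

#' Parse a JASPAR or TRANSFAC matrix collection
#'
#' JASPAR records are `>id name` headers followed by four rows
#' (`A [ 1 2 ... ]`, with or without the base letter and brackets).
#' TRANSFAC records are blocks delimited by `//`, with the matrix under a
#' `P0 A C G T` header as numbered rows of four counts. TRANSFAC matrices
#' whose rows sum to ~1 (frequency-style) are scaled to a nominal count
#' of 100.
#'
#' @param text character vector of file lines, or a single string.
#' @param format `"jaspar"` or `"transfac"`.
#' @param background,pseudocount passed to every parsed [pwm].
#' @return a named list of [pwm] objects.
#' @export
parse_pwm_collection <- function(text, format = c("jaspar", "transfac"),
                                 background = rep(0.25, 4),
                                 pseudocount = 0.25) {
  format <- match.arg(format)
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n")[[1]]
  }
  recs <- switch(format,
                 jaspar = .parse_jaspar(text),
                 transfac = .parse_transfac(text))
  out <- lapply(recs, function(r) {
    if (any(r$counts < 0)) stop("negative count in motif ", r$id)
    pwm(r$counts, r$id, source = format, background = background,
        pseudocount = pseudocount)
  })
  setNames(out, vapply(recs, `[[`, "", "id"))
}

.parse_jaspar <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR records found")
  ends <- c(hdr[-1] - 1L, length(lines))
  lapply(seq_along(hdr), function(i) {
    id <- strsplit(sub("^>", "", lines[hdr[i]]), "[ \t]+")[[1]][1]
    body <- lines[(hdr[i] + 1L):ends[i]]
    if (length(body) != 4L) {
      stop("JASPAR record ", id, " must have exactly 4 matrix rows")
    }
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt][ \t]*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("rows of unequal width in motif ", id)
    list(id = id, counts = do.call(rbind, rows))
  })
}

.parse_transfac <- function(lines) {
  lines <- lines[!grepl("^XX", lines)]
  blocks <- split(lines, cumsum(grepl("^//", lines)))
  recs <- list()
  for (blk in blocks) {
    blk <- blk[!grepl("^//", blk)]
    p0 <- grep("^P0\\b|^PO\\b", blk)
    if (length(p0) != 1L) next
    id_line <- grep("^ID\\b|^AC\\b", blk, value = TRUE)
    id <- if (length(id_line)) {
      strsplit(trimws(id_line[1]), "[ \t]+")[[1]][2]
    } else sprintf("transfac_%d", length(recs) + 1L)
    hdr <- strsplit(trimws(blk[p0]), "[ \t]+")[[1]][-1]
    if (!identical(toupper(hdr[1:4]), BASES)) {
      stop("TRANSFAC P0 header must list A C G T")
    }
    body <- blk[(p0 + 1L):length(blk)]
    body <- body[grepl("^[0-9]+\\b", body)]
    if (length(body) == 0L) stop("empty TRANSFAC matrix for ", id)
    rows <- lapply(body, function(l) {
      f <- strsplit(trimws(l), "[ \t]+")[[1]]
      as.numeric(f[2:5])
    })
    if (any(vapply(rows, function(r) any(is.na(r)), logical(1)))) {
      stop("malformed TRANSFAC row in ", id)
    }
    counts <- t(do.call(rbind, rows))  # positions were rows; transpose
    if (all(abs(colSums(counts) - 1) < 0.05)) counts <- counts * 100
    recs[[length(recs) + 1L]] <- list(id = id, counts = counts)
  }
  if (length(recs) == 0L) stop("no TRANSFAC records found")
  recs
}

#' Log-odds score matrix of a PWM, in bits
#'
#' Entry `(b, j)` is
#' `log2( (count(b, j) + pseudocount) / (colsum(j) + 4 * pseudocount) /
#' background(b) )`.
#'
#' @param x a [pwm] object.
#' @return a 4 x width numeric matrix (rows A, C, G, T), in bits.
#' @export
#' @examples
#' m <- pwm(matrix(c(2, 0, 0, 0), 4, 1), "ex")
#' log_odds(m)["A", 1]  # log2((2.25 / 3) / 0.25) = log2(3)
log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  cs <- colSums(x$counts) + 4 * x$pseudocount
  if (any(cs == 0)) stop("zero column sum with zero pseudocount")
  freq <- sweep(x$counts + x$pseudocount, 2, cs, "/")
  log2(freq / x$background)
}

#' Consensus sequence of a PWM (highest-count base per column)
#' @param x a [pwm] object.
#' @return a character string of length `pwm_width(x)`.
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$counts, 2, which.max)], collapse = "")
}

#' Generate a random sharply-peaked PWM
#'
#' Each column gets a dominant base carrying `sharpness` of the counts,
#' with the remainder spread uniformly; a simple stand-in for an
#' information-rich TF motif.
#'
#' @param width motif width in bp.
#' @param motif_id identifier.
#' @param sharpness fraction of counts on the dominant base (0.25-1).
#' @param total nominal total count per column.
#' @param seed integer seed.
#' @return a [pwm] object.
#' @export
random_pwm <- function(width = 10L, motif_id = "planted",
                       sharpness = 0.85, total = 100L, seed = 1L) {
  stopifnot(width >= 1L, sharpness >= 0.25, sharpness <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  counts <- vapply(seq_len(width), function(j) {
    dom <- sample.int(4L, 1L)
    col <- rep(total * (1 - sharpness) / 3, 4)
    col[dom] <- total * sharpness
    col
  }, numeric(4))
  pwm(counts, motif_id, source = "synthetic")
}

#' Column-shuffled decoy of a PWM
#'
#' Permutes the column order of the count matrix (guaranteed to differ
#' from the identity permutation for width >= 2), preserving the
#' information content while destroying the contiguous motif. Used as a
#' specificity control in enrichment simulations.
#'
#' @param x a [pwm] object.
#' @param motif_id identifier for the decoy.
#' @param seed integer seed.
#' @return a [pwm] object.
#' @export
shuffle_pwm_columns <- function(x, motif_id = paste0(x$motif_id, "_shuf"),
                                seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  w <- pwm_width(x)
  perm <- sample.int(w)
  if (w >= 2L) {
    while (identical(perm, seq_len(w))) perm <- sample.int(w)
  }
  pwm(x$counts[, perm, drop = FALSE], motif_id, source = "synthetic",
      background = x$background, pseudocount = x$pseudocount)
}

#' Write PWMs as a JASPAR-format file
#'
#' @param pwms a list of [pwm] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(sprintf(">%s %s", p$motif_id, p$source),
      vapply(BASES, function(b) {
        sprintf("%s [ %s ]", b,
                paste(format(p$counts[b, ], trim = TRUE), collapse = " "))
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}
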