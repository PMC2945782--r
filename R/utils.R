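# Shared helpers: seed fan-out, deterministic file headers, hashing.

#' Derive a per-stage sub-seed from a global seed
#'
#' One global seed is fanned out to independent per-stage seeds by a stable
#' arithmetic derivation, so that each pipeline stage is reproducible on its
#' own without coupling the random streams of different stages. Results stay
#' below 2^31 so they are always valid R integers.
#'
#' @param seed integer global seed.
#' @param stage integer stage index (>= 0) or a known stage name.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(7, 1)
#' derive_seed(7, "scan")
derive_seed <- function(seed, stage) {
  stages <- c(expression = 1, genome = 2, ppi = 3, dedupe = 4,
              scan = 5, enrich = 6, pipeline = 7)
  if (is.character(stage)) {
    if (!stage %in% names(stages)) stop("unknown stage name: ", stage)
    stage <- stages[[stage]]
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 1009 + 9973 * stage) %% 2147483629)
}

# Header line stamped on every pipeline output file (no timestamps: outputs
# must be byte-identical under identical seed + config).
output_header <- function(seed, config_hash) {
  sprintf("# adipomotif %s seed=%d config=%s",
          as.character(utils::packageVersion("adipomotif")),
          as.integer(seed), config_hash)
}

# md5 of an R object via its canonical JSON serialization.
hash_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# Write a data.frame as TSV with an optional leading comment header.
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
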