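# Internal helpers shared across modules.

#' Normalize a contig name
#'
#' Strips a leading "chr" prefix so that GRCh37-style ("22") and
#' GRCh38-style ("chr22") contig names compare equal.
#'
#' @param chrom Character vector of contig names.
#' @return Character vector without the "chr" prefix.
#' @keywords internal
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

# Split a star-allele label into (numeric part, suffix) for ordering,
# e.g. "*2A" -> 2, "A".  Labels without a leading number sort last.
star_key <- function(star) {
  core <- sub("^\\*", "", star)
  num <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", core)))
  suffix <- sub("^[0-9]+", "", core)
  list(num = ifelse(is.na(num), .Machine$integer.max, num), suffix = suffix)
}

# Order star-allele labels numerically then lexicographically ("*2" < "*2A" < "*10").
order_stars <- function(stars) {
  keys <- lapply(stars, star_key)
  order(vapply(keys, `[[`, integer(1), "num"),
        vapply(keys, `[[`, character(1), "suffix"))
}

sort_stars <- function(stars) stars[order_stars(stars)]

#' Normalize a diplotype alias
#'
#' Sorts the two star-allele names of an "*a/*b" alias by numeric star value
#' ascending, then lexicographically for suffixed names, so that "*17/*1"
#' and "*1/*17" refer to the same catalog row.
#'
#' @param alias A diplotype string such as `"*1/*17"`.
#' @return The normalized alias string.
#' @examples
#' normalize_diplotype("*17/*1")  # "*1/*17"
#' @export
normalize_diplotype <- function(alias) {
  vapply(alias, function(a) {
    parts <- strsplit(a, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("malformed diplotype alias: ", a, call. = FALSE)
    }
    paste(sort_stars(trimws(parts)), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Round-half-up to `digits` decimals (concordance percentages follow the
# reporting convention of printed tables, not IEEE banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
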