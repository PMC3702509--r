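# Fragment-library selection: property filtering, Tanimoto diversity
# selection on fingerprint bit-vectors, and library-versus-hits property
# distribution comparison.

#' Encode / decode fingerprint bit-vectors as hex strings
#'
#' Fingerprints travel in tables as hex strings; these helpers convert to
#' and from logical bit-vectors. Bit-vector length must be a multiple of 8.
#'
#' @param bits Logical vector.
#' @param hex Hex string (2 characters per byte).
#' @param nbits Number of bits to keep when decoding (defaults to the full
#'   encoded length).
#' @return `fp_to_hex`: a hex string; `fp_from_hex`: a logical vector.
#' @export
fp_to_hex <- function(bits) {
  stopifnot(is.logical(bits), length(bits) %% 8 == 0)
  paste(sprintf("%02x", as.integer(packBits(bits, "raw"))), collapse = "")
}

#' @rdname fp_to_hex
#' @export
fp_from_hex <- function(hex, nbits = NULL) {
  raw <- as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                                 seq(2, nchar(hex), 2)), 16L))
  bits <- as.logical(rawToBits(raw))
  if (!is.null(nbits)) bits <- bits[seq_len(nbits)]
  bits
}

# Decode a library's fingerprint column into a logical matrix (rows =
# fragments).
.fp_matrix <- function(library) {
  stopifnot("fingerprint" %in% names(library))
  if (!nrow(library)) return(matrix(logical(0), 0, 0))
  m <- t(vapply(library$fingerprint, fp_from_hex,
                logical(nchar(library$fingerprint[1]) * 4L)))
  rownames(m) <- library$id
  m
}

#' Selection criteria for a fragment library
#'
#' @param bounds Named list of per-descriptor bounds, each `c(min, max)`
#'   (use `-Inf`/`Inf` for one-sided bounds). Names must match library
#'   columns.
#' @param tanimoto_cutoff Maximal pairwise Tanimoto similarity retained by
#'   [diversity_select()], in `[0, 1]`. Default 0.85.
#' @param solubility_min Minimal solubility, uM. Default 100.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(bounds = list(), tanimoto_cutoff = 0.85,
                               solubility_min = 100) {
  if (tanimoto_cutoff < 0 || tanimoto_cutoff > 1)
    stop("'tanimoto_cutoff' must be in [0, 1]", call. = FALSE)
  for (b in bounds) {
    if (length(b) != 2 || b[1] > b[2])
      stop("each bound must be c(min, max) with min <= max", call. = FALSE)
  }
  structure(list(bounds = bounds, tanimoto_cutoff = tanimoto_cutoff,
                 solubility_min = solubility_min),
            class = "selection_criteria")
}

#' Filter a library on property bounds and the solubility gate
#'
#' Keeps records satisfying every bound; the reasons each excluded record
#' failed are recorded in the `"exclusions"` attribute.
#'
#' @param library Fragment table.
#' @param criteria A [selection_criteria()].
#' @return The filtered library; excluded rows with a `reason` column are
#'   in `attr(., "exclusions")`.
#' @export
property_filter <- function(library, criteria) {
  stopifnot(is.data.frame(library), inherits(criteria, "selection_criteria"))
  reasons <- vector("list", nrow(library))
  fail <- function(idx, why) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  }
  for (nm in names(criteria$bounds)) {
    if (!nm %in% names(library))
      stop("bound on unknown descriptor: ", nm, call. = FALSE)
    b <- criteria$bounds[[nm]]
    fail(library[[nm]] < b[1] | library[[nm]] > b[2], nm)
  }
  if (!is.null(criteria$solubility_min) && "solubility" %in% names(library))
    fail(library$solubility < criteria$solubility_min, "solubility")
  keep <- vapply(reasons, is.null, logical(1))
  out <- library[keep, , drop = FALSE]
  excl <- library[!keep, , drop = FALSE]
  if (nrow(excl))
    excl$reason <- vapply(reasons[!keep], paste, character(1), collapse = ",")
  attr(out, "exclusions") <- excl
  out
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|` on equal-length bit-vectors. Two all-zero
#' fingerprints are 1 by convention, with a warning.
#'
#' @param a,b Logical (or 0/1) vectors of equal length, or hex strings.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (is.character(a)) a <- fp_from_hex(a)
  if (is.character(b)) b <- fp_from_hex(b)
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b))
    stop("fingerprints must have equal length", call. = FALSE)
  un <- sum(a | b)
  if (un == 0) {
    warning("both fingerprints empty; Tanimoto defined as 1 by convention",
            call. = FALSE)
    return(1)
  }
  sum(a & b) / un
}

#' Greedy Tanimoto diversity selection
#'
#' A single pass in input order: a record is accepted iff its similarity to
#' every already-accepted record is strictly below the cutoff, so the
#' output's maximal pairwise similarity is `< cutoff`.
#'
#' @param library Fragment table with a `fingerprint` column.
#' @param cutoff Tanimoto cutoff in `[0, 1]`. Default 0.85.
#' @return The selected sub-library (rows in input order).
#' @export
diversity_select <- function(library, cutoff = 0.85) {
  stopifnot(is.data.frame(library))
  if (!nrow(library)) return(library)
  m <- .fp_matrix(library)
  pop <- rowSums(m)
  accepted <- integer(0)
  for (i in seq_len(nrow(m))) {
    if (!length(accepted)) {
      accepted <- i
      next
    }
    ands <- as.numeric(m[accepted, , drop = FALSE] %*% m[i, ])
    ors <- pop[accepted] + pop[i] - ands
    sim <- ifelse(ors == 0, 1, ands / ors)
    if (all(sim < cutoff)) accepted <- c(accepted, i)
  }
  library[accepted, , drop = FALSE]
}

#' Compare a property's distribution between the library and the hits
#'
#' Normalised histograms on shared bins, the per-bin hit/library fraction
#' ratio, and a per-bin enrichment flag from an exact binomial test of the
#' hit count against the library fraction.
#'
#' @param library_props Numeric vector (or library data frame) of the
#'   descriptor over the library.
#' @param hit_props Numeric vector (or hits data frame) over the hits.
#' @param descriptor Column name when data frames are supplied.
#' @param bins Number of bins, or an explicit breaks vector.
#' @param alpha Significance level of the per-bin binomial test.
#' @return Data frame with bin edges, per-group fractions (each summing to
#'   1), `ratio`, `p_value` and logical `deviates`.
#' @export
compare_distributions <- function(library_props, hit_props, descriptor = NULL,
                                  bins = 10, alpha = 0.05) {
  if (is.data.frame(library_props)) {
    stopifnot(!is.null(descriptor))
    library_props <- library_props[[descriptor]]
    hit_props <- hit_props[[descriptor]]
  }
  if (!length(library_props) || !length(hit_props))
    stop("need at least one record per group", call. = FALSE)
  rng <- range(c(library_props, hit_props))
  breaks <- if (length(bins) > 1) bins else {
    if (diff(rng) == 0) rng + c(-0.5, 0.5)
    else seq(rng[1], rng[2], length.out = bins + 1)
  }
  lib_n <- as.numeric(table(cut(library_props, breaks, include.lowest = TRUE)))
  hit_n <- as.numeric(table(cut(hit_props, breaks, include.lowest = TRUE)))
  lib_f <- lib_n / sum(lib_n)
  hit_f <- hit_n / sum(hit_n)
  pv <- vapply(seq_along(hit_n), function(i) {
    if (lib_f[i] %in% c(0, 1)) return(NA_real_)
    stats::binom.test(hit_n[i], sum(hit_n), lib_f[i])$p.value
  }, numeric(1))
  data.frame(bin_low = utils::head(breaks, -1), bin_high = breaks[-1],
             library_frac = lib_f, hit_frac = hit_f,
             ratio = ifelse(lib_f > 0, hit_f / lib_f, NA_real_),
             p_value = pv,
             deviates = !is.na(pv) & pv < alpha)
}
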