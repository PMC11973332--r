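#' Fraction of intact amplification targets under uniform DNA fragmentation
#'
#' Computes the fraction `I` of length-`L` target sequences (for example the
#' ~300 bp V4 region or the ~1,500 bp full-length 16S rRNA gene) that remain
#' unbroken when genomic DNA is idealized as being cut into consecutive
#' pieces of exactly `S` bp each:
#' \deqn{I = (S - L + 1) / S \quad \mathrm{if}\ S \ge L, \qquad I = 0
#'   \quad \mathrm{if}\ S < L.}
#' A target is intact if and only if it lies wholly within one fragment;
#' of the `S` possible phases of the cutting grid relative to the target,
#' exactly `S - L + 1` leave it unbroken (circularity ignored).
#'
#' @param S uniform fragment size in bp (numeric vector, all >= 1).
#' @param L target length in bp (numeric vector, all >= 1), recycled
#'   against `S`.
#' @return numeric vector of intact fractions in `[0, 1]`.
#' @seealso [infer_effective_fragment_size()] for the inverse,
#'   [count_intact_targets()] for the Monte-Carlo oracle.
#' @examples
#' intact_fraction(1000, 1500) # fully fragmented below target length -> 0
#' intact_fraction(1500, 300)  # 1201/1500
#' @export
intact_fraction <- function(S, L) {
  if (length(S) == 0L || length(L) == 0L) stop("S and L must be non-empty")
  if (anyNA(S) || anyNA(L)) stop("S and L must not contain NA")
  if (any(S < 1) || any(L < 1)) stop("S and L must be >= 1 bp")
  ifelse(S < L, 0, (S - L + 1) / S)
}

#' Full-length versus partial-amplicon intactness ratio
#'
#' Ratio `I(S, L_full) / I(S, L_partial)` of intact-target fractions for a
#' long amplicon target (default the 1,500 bp full-length 16S rRNA gene)
#' versus a short one (default the 300 bp V4 region), as a function of the
#' uniform fragment size `S`. Species with more fragmented DNA (small `S`)
#' have ratios near 0 and are under-represented by full-length amplicon
#' sequencing relative to V4 sequencing; the ratio rises monotonically to 1
#' as `S` grows.
#'
#' @param S uniform fragment size in bp (vectorized).
#' @param L_full long target length in bp, default 1500.
#' @param L_partial short target length in bp, default 300.
#' @return numeric vector in `[0, 1]`; `NA` where `I(S, L_partial) = 0`
#'   (ratio undefined, `S` below both target lengths).
#' @export
amplicon_bias_ratio <- function(S, L_full = 1500, L_partial = 300) {
  num <- intact_fraction(S, L_full)
  den <- intact_fraction(S, L_partial)
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

#' Effective uniform fragment size implied by an observed intact fraction
#'
#' Closed-form inverse of [intact_fraction()]: given the fraction
#' `I` of intact length-`L` targets, the uniform fragment size satisfying
#' `I = (S - L + 1)/S` is `S = (L - 1)/(1 - I)`.
#'
#' @param I_observed observed intact fraction, strictly between 0 and 1.
#' @param L target length in bp.
#' @return effective fragment size `S` in bp (numeric, possibly
#'   non-integer; it is an idealized model parameter, not a measurement).
#' @export
infer_effective_fragment_size <- function(I_observed, L) {
  if (anyNA(I_observed) || anyNA(L)) stop("arguments must not contain NA")
  if (any(L < 1)) stop("L must be >= 1 bp")
  if (any(I_observed >= 1))
    stop("I_observed = 1 implies unfragmented DNA (S infinite); no finite S")
  if (any(I_observed <= 0))
    stop("I_observed = 0 only bounds the fragment size (S < L); ",
         "no point estimate is inferable")
  (L - 1) / (1 - I_observed)
}

#' Predict amplicon-based relative abundances under fragmentation bias
#'
#' Given per-species true abundances, effective uniform fragment sizes and
#' 16S rRNA gene copy numbers, predicts the relative abundances an
#' amplicon-based survey of a length-`L` target would report: each species'
#' weight is its true abundance times its intact-target fraction
#' `I(S, L)`, optionally times its gene copy number, renormalized to 1.
#'
#' @param specs data frame with columns `species`, `S` (effective fragment
#'   size, bp), `copy_number` (positive integer 16S copies; optional,
#'   default 1) and `true_abundance` (fractions summing to 1).
#' @param L amplicon target length in bp (300 for V4, 1500 for the
#'   full-length gene).
#' @param use_copy_number multiply weights by `copy_number`? Default
#'   `FALSE`: copy number is reported as a bias direction, not fitted.
#' @return an [abundance_table] with `mode = "amplicon"`.
#' @export
predict_amplicon_abundance <- function(specs, L, use_copy_number = FALSE) {
  stopifnot(is.data.frame(specs),
            all(c("species", "S", "true_abundance") %in% names(specs)))
  if (!"copy_number" %in% names(specs)) specs$copy_number <- 1L
  if (abs(sum(specs$true_abundance) - 1) > 1e-6)
    stop("true abundances must sum to 1")
  if (any(specs$copy_number < 1)) stop("copy_number must be >= 1")
  w <- specs$true_abundance * intact_fraction(specs$S, L)
  if (use_copy_number) w <- w * specs$copy_number
  if (all(w == 0))
    stop("all species have zero predicted amplicon weight (all S < L)")
  abundance_table(setNames(w / sum(w), specs$species),
                  sample_id = "predicted", mode = "amplicon")
}
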