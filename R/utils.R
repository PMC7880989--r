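#' @import data.table
#' @importFrom stats rnorm runif rbinom qnorm qlogis plogis pnorm pt pchisq
#'   glm lm binomial gaussian as.formula coef vcov sd var cor complete.cases
#'   setNames model.matrix
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible per-stage seed from a global seed
#'
#' All stochastic stages draw their seed from the pipeline's single global
#' seed so that stages are isolated (re-running one stage does not perturb
#' another) while the whole run stays deterministic.
#'
#' @param seed Global integer seed.
#' @param stage Stage label (character) or integer offset.
#' @return An integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stage) {
  off <- if (is.character(stage)) sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) else as.integer(stage)
  as.integer((as.numeric(seed) * 48271 + off * 16807) %% 2147483647)
}

## reverse-complement of plain SNP alleles
complement_allele <- function(a) {
  chartr("ACGTacgt", "TGCAtgca", a)
}

is_ambiguous_pair <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & toupper(a2) == complement_allele(toupper(a1))
}

minor_af <- function(f) pmin(f, 1 - f)

## stable key for one catalog association
catalog_key <- function(rsid, phenotype, subphenotype, ancestry_label) {
  sub <- ifelse(is.na(subphenotype) | subphenotype == "", ".", subphenotype)
  paste(rsid, phenotype, sub, ancestry_label, sep = "|")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
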