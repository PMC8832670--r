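# Seeded generator of succinylation-like fragment datasets with planted
# positional signal, so the whole pipeline is testable without external
# downloads.

#' Specification for the synthetic fragment generator
#'
#' The generator emulates the structure of curated succinylation-site
#' benchmarks: 51-residue windows centred on a lysine, a configurable
#' positive:negative imbalance (1:10 by default, mirroring real site
#' tables), and class-dependent residue distributions at a chosen set of
#' planted offsets. `effect_size` is the total-variation distance between
#' the positive-class and negative-class residue distributions at every
#' planted offset; all other offsets draw from the shared background.
#'
#' @param n_pos,n_neg Positive / negative fragment counts (default
#'   500 / 5000).
#' @param planted_offsets Offsets (excluding 0) carrying class signal
#'   (default `c(-2, 1)`).
#' @param effect_size Total-variation distance in `[0, 0.95]` between the
#'   class-conditional residue distributions at planted offsets (default
#'   0.5).
#' @param background Residue distribution over the 20 standard amino
#'   acids for all non-planted offsets (default uniform). A skewed
#'   background exercises zero-count contingency columns downstream.
#' @param flank Residues each side of the K (default 25, 51-mers).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return Object of class `chidt_genspec`.
#' @export
generator_spec <- function(n_pos = 500L, n_neg = 5000L,
                           planted_offsets = c(-2L, 1L),
                           effect_size = 0.5,
                           background = rep(1 / 20, 20L),
                           flank = 25L, seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) stop("need at least one sample in each class")
  if (effect_size < 0 || effect_size > 0.95)
    stop("effect_size must be in [0, 0.95]")
  if (length(background) != 20L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop("background must be a 20-residue probability distribution")
  if (any(planted_offsets == 0L) || any(abs(planted_offsets) > flank))
    stop("planted offsets must be non-zero and within the flank")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 planted_offsets = as.integer(planted_offsets),
                 effect_size = effect_size,
                 background = background / sum(background),
                 flank = as.integer(flank), seed = as.integer(seed)),
            class = "chidt_genspec")
}

# positive-class residue distribution at a planted offset: shift
# `effect_size` of probability mass onto a favoured residue subset.
# With a uniform background and effect <= 0.5 the favoured half holds 10
# residues; larger effects concentrate on fewer residues so the requested
# total-variation distance stays attainable.
planted_distribution <- function(background, effect_size) {
  if (effect_size == 0) return(background)
  k <- if (effect_size <= 0.5) 10L else max(1L, floor(20 * (1 - effect_size)))
  fav <- order(background, decreasing = TRUE)[seq_len(k)]
  w <- effect_size / (1 - sum(background[fav]))
  if (w > 1) stop("effect_size unattainable for this background")
  p <- (1 - w) * background
  p[fav] <- p[fav] + w * background[fav] / sum(background[fav])
  p / sum(p)
}

#' Generate labelled synthetic site fragments
#'
#' Reproducible for a fixed spec (including seed). Marginal residue
#' frequencies at planted offsets differ between classes by the configured
#' total-variation distance; non-planted offsets are class-independent;
#' offset 0 is always K.
#'
#' @param spec A `chidt_genspec` from [generator_spec()].
#' @return A labelled `chidt_fragments` data frame (`label` 1 for the
#'   `n_pos` positives, then 0 for the `n_neg` negatives).
#' @export
generate_fragments <- function(spec) {
  stopifnot(inherits(spec, "chidt_genspec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  flank <- spec$flank
  width <- 2L * flank + 1L
  n <- spec$n_pos + spec$n_neg
  labels <- rep(c(1L, 0L), c(spec$n_pos, spec$n_neg))
  pos_dist <- planted_distribution(spec$background, spec$effect_size)

  mat <- matrix("", n, width)
  for (col in seq_len(width)) {
    off <- col - flank - 1L
    if (off == 0L) { mat[, col] <- "K"; next }
    if (off %in% spec$planted_offsets) {
      mat[labels == 1L, col] <- sample(AA20, spec$n_pos, replace = TRUE,
                                       prob = pos_dist)
      mat[labels == 0L, col] <- sample(AA20, spec$n_neg, replace = TRUE,
                                       prob = spec$background)
    } else {
      mat[, col] <- sample(AA20, n, replace = TRUE, prob = spec$background)
    }
  }
  out <- data.frame(protein_id = sprintf("SYN%06d", seq_len(n)),
                    position = rep(flank + 1L, n),
                    fragment = apply(mat, 1L, paste, collapse = ""),
                    label = labels,
                    stringsAsFactors = FALSE)
  attr(out, "flank") <- flank
  class(out) <- c("chidt_fragments", class(out))
  out
}

#' Write synthetic fragments as FASTA plus a TSV site table
#'
#' Each fragment becomes one synthetic protein record whose sequence is
#' the 51-mer itself, with the candidate K at the central position; the
#' site table rows point at that K. The files round-trip through
#' [load_sites()] and [make_fragments()] to the identical fragment set.
#'
#' @param fragments A `chidt_fragments` data frame.
#' @param fasta,sites Output paths.
#' @export
write_synthetic_dataset <- function(fragments, fasta, sites) {
  set <- Biostrings::AAStringSet(fragments$fragment)
  names(set) <- fragments$protein_id
  Biostrings::writeXStringSet(set, fasta)
  utils::write.table(data.frame(protein_id = fragments$protein_id,
                                position = fragments$position,
                                label = fragments$label),
                     sites, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, sites = sites))
}
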