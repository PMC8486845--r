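# Unified nearest-neighbour thermodynamic parameters for DNA duplexes
# (SantaLucia, PNAS 95:1460, 1998; 1 M NaCl). DeltaH in kcal/mol, DeltaS in
# cal/(mol K) per dinucleotide step, 5'->3' on the given strand. Salt
# corrections are deliberately not applied (the zipper model treats the
# junction in ambient conditions without electrostatics).
NN_TABLE <- data.frame(
  step = c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG"),
  dH   = c(-7.9, -7.2, -7.2, -8.5, -8.4, -7.8, -8.2, -10.6, -9.8, -8.0),
  dS   = c(-22.2, -20.4, -21.3, -22.7, -22.4, -21.0, -22.2, -27.2, -24.4, -19.9)
)
# duplex initiation terms (per terminal base pair)
NN_INIT <- data.frame(
  term = c("G", "C", "A", "T"),
  dH   = c(0.1, 0.1, 2.3, 2.3),
  dS   = c(-2.8, -2.8, 4.1, 4.1)
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a base string
#' @param sequence base string over `A`, `C`, `G`, `T`.
#' @return the reverse complement string.
#' @export
reverse_complement <- function(sequence) {
  b <- seq_bases(sequence)
  paste(rev(unname(COMPLEMENT[b])), collapse = "")
}

seq_bases <- function(sequence) {
  b <- strsplit(toupper(sequence), "")[[1]]
  if (!all(b %in% c("A", "C", "G", "T"))) {
    abort("sequence contains characters outside A/C/G/T")
  }
  b
}

nn_lookup <- function(steps) {
  tab <- setNames(seq_len(nrow(NN_TABLE)), NN_TABLE$step)
  # a step read on the complementary strand has identical thermodynamics
  rc_step <- vapply(NN_TABLE$step, reverse_complement, character(1))
  tab2 <- setNames(seq_len(nrow(NN_TABLE)), rc_step)
  idx <- ifelse(is.na(tab[steps]), tab2[steps], tab[steps])
  if (anyNA(idx)) abort("unknown dinucleotide step")
  idx
}

#' Per-base-pair opening free energies of a duplex
#'
#' Maps a duplex (given as one strand, 5' to 3', with the tethered,
#' fork-side end first) to the opening cost of each base pair along the
#' zipper coordinate, from the embedded unified nearest-neighbour table at
#' `temperature`. Opening pair `i` (for `i < n`) consumes the stacking
#' step between pairs `i` and `i+1`, so its cost is `-DeltaG` of that
#' dinucleotide step; the final, distal pair carries the duplex initiation
#' cost (mean of the two terminal initiation terms, which keeps the total
#' invariant under reverse complementation). All costs are positive at 300 K
#' (the closed duplex is favoured) and their sum is the total duplex
#' stability in this convention.
#'
#' @param sequence base string (one strand, 5'->3').
#' @param temperature K.
#' @return tibble `pair`, `step` (dinucleotide or terminal base),
#'   `dg_open` (kcal/mol).
#' @export
#' @examples
#' nn_step_free_energies("GCGC", 300)
nn_step_free_energies <- function(sequence, temperature = 300) {
  b <- seq_bases(sequence)
  n <- length(b)
  if (n < 2) abort("need at least 2 base pairs")
  steps <- paste0(b[-n], b[-1])
  idx <- nn_lookup(steps)
  dg_step <- NN_TABLE$dH[idx] - temperature * NN_TABLE$dS[idx] / 1000
  iterm <- match(b[c(1, n)], NN_INIT$term)
  dg_term <- sum(NN_INIT$dH[iterm] - temperature * NN_INIT$dS[iterm] / 1000) / 2
  tibble::tibble(
    pair = seq_len(n),
    step = c(steps, b[n]),
    dg_open = c(-dg_step, dg_term)
  )
}
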