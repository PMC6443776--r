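#' Parameters of the tandem-repeat silk-protein sequence model
#'
#' Each tandem unit is PAB (polyalanine block) + NPAB (non-polyalanine
#' block); the NPAB is a Gly-X dipeptide stretch, then a short insert of
#' bulky residues (Ser/Val/Tyr), then a mixed Gly-X / Gly-Gly-X stretch.
#' Defaults 22/45/6/87 give 160-residue units, echoing a heavy-chain fibroin
#' with >20-residue polyalanine runs, ~45 residues between PAB and insert,
#' and a ~5–8 residue non-repeated insert.
#'
#' @param n_motifs number of tandem units (>= 1).
#' @param pab_length polyalanine run length (residues).
#' @param npab_pre_insert_length Gly-X stretch between PAB and insert.
#' @param insert_length insert length (residues).
#' @param npab_post_insert_length mixed Gly-X / Gly-Gly-X stretch.
#' @param gx_fraction probability that a tile in the post-insert stretch is
#'   Gly-X rather than Gly-Gly-X.
#' @param seed integer RNG seed.
#' @return object of class `sequence_params`; `$motif_length` is the unit
#'   length.
#' @export
sequence_params <- function(n_motifs = 5L,
                            pab_length = 22L,
                            npab_pre_insert_length = 45L,
                            insert_length = 6L,
                            npab_post_insert_length = 87L,
                            gx_fraction = 0.5,
                            seed = NULL) {
  n_motifs <- as.integer(n_motifs)
  if (n_motifs < 1L) stop("n_motifs must be >= 1")
  lens <- c(pab_length, npab_pre_insert_length, insert_length,
            npab_post_insert_length)
  if (any(lens < 1)) stop("all segment lengths must be >= 1")
  if (gx_fraction < 0 || gx_fraction > 1)
    stop("gx_fraction must lie in [0, 1]")
  structure(list(n_motifs = n_motifs, pab_length = as.integer(pab_length),
                 npab_pre_insert_length = as.integer(npab_pre_insert_length),
                 insert_length = as.integer(insert_length),
                 npab_post_insert_length =
                   as.integer(npab_post_insert_length),
                 motif_length = as.integer(sum(lens)),
                 gx_fraction = gx_fraction, seed = seed),
            class = "sequence_params")
}

## composition weights of the stated dipeptide/tripeptide chemistry
GX_X_WEIGHTS <- c(A = 0.6, S = 0.4)
GGX_X_WEIGHTS <- c(A = 0.6, Y = 0.4)
INSERT_WEIGHTS <- c(S = 0.4, V = 0.3, Y = 0.3)

sample_w <- function(n, w) sample(names(w), n, replace = TRUE, prob = w)

## Gly-X stretch of length n (odd positions G); the residue adjacent to the
## insert is forced away from {S,V,Y} so ground-truth insert spans stay
## exactly recoverable
gx_stretch <- function(n, guard_last = FALSE) {
  res <- character(n)
  odd <- seq(1, n, by = 2)
  res[odd] <- "G"
  even <- seq_len(n)[-odd]
  if (length(even)) res[even] <- sample_w(length(even), GX_X_WEIGHTS)
  if (guard_last && n %% 2 == 0) res[n] <- "A"
  res
}

ggx_mixed_stretch <- function(n, gx_fraction) {
  res <- character(0)
  while (length(res) < n) {
    if (stats::runif(1) < gx_fraction)
      res <- c(res, "G", sample_w(1, GX_X_WEIGHTS))
    else
      res <- c(res, "G", "G", sample_w(1, GGX_X_WEIGHTS))
  }
  res <- res[seq_len(n)]
  # the stretch abuts the next polyalanine block: a terminal Ala would fuse
  # with it and shift the ground-truth PAB span
  if (res[n] == "A") res[n] <- "S"
  res
}

#' Generate a tandem-repeat silk-like protein sequence with ground truth
#'
#' @param params a [sequence_params].
#' @return list of class `synth_sequence`: `sequence` (a single character
#'   string) and `truth` (a data.frame of 1-based inclusive spans per unit:
#'   `pab_start/end`, `npab_start/end`, `insert_start/end`,
#'   `motif_start/end`).
#' @export
generate_sequences <- function(params) {
  stopifnot(inherits(params, "sequence_params"))
  with_seed(params$seed, {
    units <- vector("list", params$n_motifs)
    spans <- vector("list", params$n_motifs)
    off <- 0L
    for (m in seq_len(params$n_motifs)) {
      pab <- strrep("A", params$pab_length)
      pre <- gx_stretch(params$npab_pre_insert_length, guard_last = TRUE)
      ins <- sample_w(params$insert_length, INSERT_WEIGHTS)
      post <- ggx_mixed_stretch(params$npab_post_insert_length,
                                params$gx_fraction)
      units[[m]] <- paste0(pab, paste(pre, collapse = ""),
                           paste(ins, collapse = ""),
                           paste(post, collapse = ""))
      pab_start <- off + 1L
      pab_end <- off + params$pab_length
      ins_start <- pab_end + params$npab_pre_insert_length + 1L
      spans[[m]] <- data.frame(
        motif = m,
        motif_start = pab_start, motif_end = off + params$motif_length,
        pab_start = pab_start, pab_end = pab_end,
        npab_start = pab_end + 1L, npab_end = off + params$motif_length,
        insert_start = ins_start,
        insert_end = ins_start + params$insert_length - 1L)
      off <- off + params$motif_length
    }
    structure(list(sequence = paste(unlist(units), collapse = ""),
                   truth = do.call(rbind, spans),
                   params = params),
              class = "synth_sequence")
  })
}

#' Read / write protein FASTA (Biostrings-backed)
#'
#' @param sequences named character vector of protein sequences.
#' @param path FASTA file path.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `path` invisibly.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}
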