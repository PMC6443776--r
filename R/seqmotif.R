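AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_protein <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad))
    stop(sprintf("invalid residue '%s' at position %d", chars[bad[1]],
                 bad[1]))
  chars
}

#' Maximal polyalanine runs
#'
#' Finds maximal runs of 'A' of length \eqn{\ge} `min_run`, left to right.
#'
#' @param sequence protein sequence (single string, 20-letter alphabet).
#' @param min_run minimum run length (default 10, separating the >20-residue
#'   polyalanine blocks of this fibroin from the 5–8-residue runs of
#'   spidroins).
#' @return data.frame with 1-based inclusive columns `start`, `end`,
#'   `length`.
#' @export
find_polyalanine_blocks <- function(sequence, min_run = 10L) {
  check_protein(sequence)
  m <- gregexpr("A+", sequence)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  len <- attr(m, "match.length")
  keep <- len >= min_run
  data.frame(start = as.integer(m[keep]),
             end = as.integer(m[keep] + len[keep] - 1L),
             length = as.integer(len[keep]))
}

## best SVY-rich window of length 4-10 inside [from, to]; returns NULL if
## the best fraction is below the threshold
locate_insert <- function(chars, from, to, min_len = 4L, max_len = 10L,
                          threshold = 0.7) {
  svy <- cumsum(c(0L, chars %in% c("S", "V", "Y")))
  best <- NULL
  for (L in seq(min_len, max_len)) {
    starts <- seq(from, to - L + 1L)
    if (!length(starts) || starts[1] > to - L + 1L) next
    frac <- (svy[starts + L] - svy[starts]) / L
    i <- which.max(frac)   # leftmost max
    cand <- list(start = starts[i], end = starts[i] + L - 1L,
                 fraction = frac[i], length = L)
    if (is.null(best) || cand$fraction > best$fraction + 1e-12 ||
        (abs(cand$fraction - best$fraction) <= 1e-12 &&
         cand$length > best$length))
      best <- cand
  }
  if (is.null(best) || best$fraction < threshold) return(NULL)
  best
}

#' Segment PAB+NPAB tandem repeat motifs
#'
#' Each motif spans from the start of one polyalanine block (PAB) to the
#' residue before the start of the next, so `n` PAB blocks yield `n - 1`
#' complete motifs; the final PAB begins an incomplete terminal unit which
#' is reported separately in `attr(, "incomplete_tail")`. Within each NPAB
#' the short non-repeated insert is located as the best window of length
#' 4–10 maximising the Ser/Val/Tyr fraction (threshold 70%, leftmost then
#' longest on ties); motifs without such a window carry `NA` insert spans.
#'
#' @param sequence protein sequence (single string).
#' @param pab_blocks result of [find_polyalanine_blocks()] (recomputed with
#'   defaults when omitted).
#' @return data.frame of class `repeat_motifs` with 1-based inclusive spans
#'   `motif_start/end`, `pab_start/end`, `npab_start/end`,
#'   `insert_start/end`, `motif_length`; empty (with a warning) when fewer
#'   than two PABs are present.
#' @export
segment_tandem_motifs <- function(sequence,
                                  pab_blocks =
                                    find_polyalanine_blocks(sequence)) {
  chars <- check_protein(sequence)
  empty <- data.frame(motif_start = integer(0), motif_end = integer(0),
                      pab_start = integer(0), pab_end = integer(0),
                      npab_start = integer(0), npab_end = integer(0),
                      insert_start = integer(0), insert_end = integer(0),
                      motif_length = integer(0))
  if (nrow(pab_blocks) < 2L) {
    warning("fewer than two polyalanine blocks: no complete motif",
            call. = FALSE)
    return(structure(empty, class = c("repeat_motifs", "data.frame")))
  }
  n <- nrow(pab_blocks) - 1L
  out <- empty[rep(1L, 0L), ]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ms <- pab_blocks$start[i]
    me <- pab_blocks$start[i + 1L] - 1L
    ns <- pab_blocks$end[i] + 1L
    ins <- locate_insert(chars, ns, me)
    rows[[i]] <- data.frame(
      motif_start = ms, motif_end = me,
      pab_start = ms, pab_end = pab_blocks$end[i],
      npab_start = ns, npab_end = me,
      insert_start = if (is.null(ins)) NA_integer_ else ins$start,
      insert_end = if (is.null(ins)) NA_integer_ else ins$end,
      motif_length = me - ms + 1L)
  }
  out <- do.call(rbind, rows)
  attr(out, "incomplete_tail") <-
    c(start = pab_blocks$start[n + 1L], end = nchar(sequence))
  structure(out, class = c("repeat_motifs", "data.frame"))
}

#' NPAB dipeptide/tripeptide chemistry report
#'
#' Greedy left-to-right tiling of the NPAB with Gly-Gly-X tripeptide and
#' Gly-X dipeptide tiles (X any residue but Gly; the longer tile wins when
#' both match), reporting the fraction of NPAB residues covered by each tile
#' family, plus the Gly+Ala molar fraction of the whole sequence.
#'
#' @param motif one row of [segment_tandem_motifs()] output (or any list
#'   with `npab_start`, `npab_end`).
#' @param sequence the protein sequence the motif indexes into.
#' @return list: `gx_fraction`, `ggx_fraction`, `unclassified_fraction` (of
#'   NPAB residues), `gly_ala_fraction` (whole sequence).
#' @export
classify_npab_chemistry <- function(motif, sequence) {
  chars <- check_protein(sequence)
  ns <- motif$npab_start; ne <- motif$npab_end
  stopifnot(ns >= 1, ne <= length(chars), ns <= ne)
  i <- ns
  gx <- 0L; ggx <- 0L
  while (i <= ne) {
    if (i + 2L <= ne && chars[i] == "G" && chars[i + 1L] == "G" &&
        chars[i + 2L] != "G") {
      ggx <- ggx + 3L; i <- i + 3L
    } else if (i + 1L <= ne && chars[i] == "G" && chars[i + 1L] != "G") {
      gx <- gx + 2L; i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  n <- ne - ns + 1L
  list(gx_fraction = gx / n,
       ggx_fraction = ggx / n,
       unclassified_fraction = (n - gx - ggx) / n,
       gly_ala_fraction = mean(chars %in% c("G", "A")))
}

#' Map a repeat-motif residue census to phase lengths
#'
#' The crystal-forming stretch (PAB plus the NPAB residues up to the insert)
#' maps to a crystalline length of `residue_rise` nm per residue in the
#' extended \eqn{\beta} conformation; the remaining NPAB maps to an
#' amorphous contour length, and its shrinkage relative to a measured
#' amorphous phase thickness is
#' \eqn{(contour - thickness)/contour \times 100}.
#'
#' @param pab_residues residues in the PAB.
#' @param npab_crystal_residues NPAB residues between PAB end and insert.
#' @param npab_amorphous_residues remaining NPAB residues (insert onward).
#' @param residue_rise axial rise per residue in the \eqn{\beta}-sheet, nm
#'   (default 0.35).
#' @param amorphous_phase_thickness measured phase-I thickness in nm
#'   (optional; enables the shrinkage and predicted-long-period fields).
#' @return object of class `sequence_structure_map`: residue counts,
#'   `crystal_length` (nm), `amorphous_contour` (nm),
#'   `amorphous_shrinkage` (percent or NA), `predicted_long_period` (nm or
#'   NA).
#' @export
map_to_phase_lengths <- function(pab_residues, npab_crystal_residues,
                                 npab_amorphous_residues,
                                 residue_rise = 0.35,
                                 amorphous_phase_thickness = NULL) {
  counts <- c(pab_residues, npab_crystal_residues, npab_amorphous_residues)
  if (any(counts < 0)) stop("residue counts must be non-negative")
  if (residue_rise <= 0) stop("residue_rise must be positive")
  n_cryst <- pab_residues + npab_crystal_residues
  crystal_length <- n_cryst * residue_rise
  contour <- npab_amorphous_residues * residue_rise
  shrink <- NA_real_
  pred_lp <- NA_real_
  if (!is.null(amorphous_phase_thickness)) {
    if (contour > 0)
      shrink <- (contour - amorphous_phase_thickness) / contour * 100
    pred_lp <- crystal_length + amorphous_phase_thickness
  }
  structure(list(n_crystal_residues = n_cryst,
                 n_amorphous_residues = npab_amorphous_residues,
                 residue_rise = residue_rise,
                 crystal_length = crystal_length,
                 amorphous_contour = contour,
                 amorphous_shrinkage = shrink,
                 predicted_long_period = pred_lp),
            class = "sequence_structure_map")
}

#' @export
print.sequence_structure_map <- function(x, ...) {
  cat(sprintf(
    "<sequence_structure_map> %d crystal residues -> %s nm; %d amorphous residues -> %s nm contour%s\n",
    x$n_crystal_residues, format(round_half_up(x$crystal_length, 1)),
    x$n_amorphous_residues, format(round_half_up(x$amorphous_contour, 1)),
    if (is.na(x$amorphous_shrinkage)) ""
    else sprintf(" (shrinkage %.0f%%)",
                 round_half_up(x$amorphous_shrinkage, 0))))
  invisible(x)
}

#' Residue census of segmented motifs
#'
#' Median per-motif counts of PAB, crystal-forming NPAB (PAB end to insert
#' start) and amorphous NPAB (insert onward) residues.
#'
#' @param motifs a [segment_tandem_motifs()] result with located inserts.
#' @return list with `pab`, `npab_crystal`, `npab_amorphous`.
#' @export
motif_census <- function(motifs) {
  m <- motifs[!is.na(motifs$insert_start), , drop = FALSE]
  if (!nrow(m)) stop("no motif with a located insert")
  list(pab = stats::median(m$pab_end - m$pab_start + 1L),
       npab_crystal = stats::median(m$insert_start - m$pab_end - 1L),
       npab_amorphous = stats::median(m$npab_end - m$insert_start + 1L))
}

#' Write motif spans as a BED-like TSV
#'
#' Tab-separated spans, 1-based inclusive (stated in the header comment).
#'
#' @param motifs a [segment_tandem_motifs()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based, inclusive", con)
  utils::write.table(as.data.frame(motifs), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
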