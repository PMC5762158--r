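#' Per-residue conservation profile from a multiple sequence alignment
#'
#' For every ungapped column of the chosen reference sequence, the score is
#' the fraction of alignment sequences (reference included) carrying the
#' reference residue; gaps count as mismatches. Identity-to-reference is
#' deliberately simple and reproducible; the scoring function can be
#' swapped via `score_fun(column_chars, ref_char)`.
#'
#' @param alignment an `alignment_fasta` from [read_fasta_alignment()]
#' @param reference_id identifier of the reference sequence
#' @param score_fun optional scoring function; default identity fraction
#' @return object of class `conservation_profile`: data.frame with
#'   `position` (1-based ungapped reference position), `column` (alignment
#'   column), `residue` (reference amino acid), `score` in \[0, 1\]
#' @export
conservation_profile <- function(alignment, reference_id, score_fun = NULL) {
  stopifnot(inherits(alignment, "alignment_fasta"))
  i <- match(reference_id, alignment$ids)
  if (is.na(i))
    stop("conservation_profile: reference id '", reference_id,
         "' not in alignment")
  mat <- alignment_matrix(alignment)
  refrow <- mat[i, ]
  cols <- which(refrow != "-")
  if (is.null(score_fun))
    score_fun <- function(column, ref) mean(column == ref)
  score <- vapply(cols, function(cc) score_fun(mat[, cc], refrow[cc]), 0.0)
  out <- data.frame(position = seq_along(cols), column = cols,
                    residue = refrow[cols], score = score)
  attr(out, "reference_id") <- reference_id
  attr(out, "n_sequences") <- length(alignment$ids)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Map conservation scores onto a model chain (b-factor column)
#'
#' Reference position i is matched to residue `resno_offset + i` of the
#' chain; the chain's amino-acid sequence is checked against the reference
#' sequence and the mapping aborts if more than `max_mismatch` of the
#' mapped residues disagree. Missing residues (truncated loops) are flagged
#' and skipped. The score lands in the b-factor field for structure
#' coloring.
#'
#' @param profile a [conservation_profile()]
#' @param model an [atomic_model()]
#' @param chain chain id to color
#' @param resno_offset residue number of reference position 1 minus one;
#'   default aligns position 1 with the chain's first residue
#' @param max_mismatch abort threshold, fraction of mapped residues
#' @return list with `model` (scores in b), `mapped` (data.frame), and
#'   `missing` (reference positions absent from the chain)
#' @export
map_scores_to_model <- function(profile, model, chain, resno_offset = NULL,
                                max_mismatch = 0.05) {
  a <- model$atoms
  in_chain <- a$chain == chain & a$type == "ATOM"
  if (!any(in_chain)) stop("map_scores_to_model: chain '", chain, "' absent")
  if (is.null(resno_offset))
    resno_offset <- min(a$resno[in_chain]) - 1L
  target <- profile$position + resno_offset
  present <- target %in% a$resno[in_chain]
  # sequence agreement over mapped residues
  res_of <- function(rn) {
    rs <- unique(a$resname[in_chain & a$resno == rn])
    unname(aa3to1[rs[1]])
  }
  mapped_rn <- target[present]
  model_aa <- vapply(mapped_rn, res_of, "")
  ref_aa <- as.character(profile$residue[present])
  cmp <- !is.na(model_aa)
  mism <- sum(model_aa[cmp] != ref_aa[cmp]) / max(sum(cmp), 1)
  if (mism > max_mismatch)
    stop(sprintf("map_scores_to_model: %.1f%% sequence mismatch (limit %.1f%%)",
                 100 * mism, 100 * max_mismatch))
  for (j in which(present)) {
    rows <- which(in_chain & a$resno == target[j])
    model$atoms$b[rows] <- profile$score[j]
  }
  list(model = model,
       mapped = data.frame(position = profile$position[present],
                           resno = mapped_rn, score = profile$score[present],
                           model_aa = model_aa, ref_aa = ref_aa,
                           mismatch = model_aa != ref_aa),
       missing = profile$position[!present])
}
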