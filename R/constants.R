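## Packaged reference motifs, patterns, signature motifs, kinase rules
## and the two human N-terminal peptides of the Twist1/Twist2 pair.
## Everything here is self-checked at construction time: each group's
## mammalian motif must match its own pattern and signature and fail the
## other group's signature.

#' Packaged Twist1/Twist2 motif and kinase constants
#'
#' Returns the reference strings and rules of the Twist1/Twist2
#' comparative analysis: the strictly conserved mammalian N-terminal
#' motifs of each paralog, their PROSITE-format group patterns, the two
#' shared sub-motifs, the per-paralog signature motifs (minimal
#' discriminative cores), the four serine/threonine kinase consensus
#' rules (GSK3, BARK, LKB1, CK2), and the two human N-terminal peptides
#' used in the worked kinase examples.
#'
#' Self-consistency is asserted on construction: each mammalian motif
#' matches its own group pattern and signature, and neither matches the
#' other group's signature.
#'
#' @return a list with components \code{t1_motif}, \code{t2_motif}
#'   (mammalian motif strings), \code{t1_pattern}, \code{t2_pattern},
#'   \code{submotif1}, \code{submotif2}, \code{t1_signature},
#'   \code{t2_signature} (all \code{\linkS4class{PrositePattern}}),
#'   \code{kinase_rules} (named list of
#'   \code{\linkS4class{KinaseRule}}), and \code{t1_peptide},
#'   \code{t2_peptide}.
#' @examples
#' tc <- twistConstants()
#' prositeText(tc$t1_signature)
#' @export
twistConstants <- function() {
  out <- list(
    t1_motif = "SSSPVSPADDSLSNSEEE",
    t2_motif = "SSSPVSPVDSLGTSEEE",
    t1_pattern = parseProsite(
      "[GSA]-[SNR]-S-P-[VEA]-S-P-[AV]-D-D-S-[LVA]-[SG]-N-S-E-[EG]-E"),
    t2_pattern = parseProsite(
      "S-[SG]-[SC]-P-[VG]-S-P-V-D-S-[LV]-[VG]-T-S-E-E-E"),
    submotif1 = parseProsite("[GSA]-[SGNR]-[SC]-P-[VGEA]-S-P-[VA]-D"),
    submotif2 = parseProsite("[TN]-S-E-[EG]-E"),
    t1_signature = parseProsite(
      "P-[VEA]-S-P-[VA]-D-D-S-[LVA]-[SG]-N-S-E"),
    t2_signature = parseProsite(
      "P-[GV]-S-P-V-D-S-[LV]-[VG]-T-S-E"),
    kinase_rules = list(
      GSK3 = kinaseRule("GSK3", "pS-X-X-X-pS-P", siteIndex = 1L),
      BARK = kinaseRule("BARK", "X-E-X-pS-X-X"),
      LKB1 = kinaseRule("LKB1", "X-L-X-pT-X-X"),
      CK2  = kinaseRule("CK2",  "pS/T-X-D/E-D/E/pS-D/E", siteIndex = 1L)),
    t1_peptide = "MMQDVSSSPVSPADDSLSNSEEE",
    t2_peptide = "MEEGSSSPVSPVDSLGTSEEE")

  ok <- matchesProsite(out$t1_pattern, out$t1_motif) &&
    matchesProsite(out$t2_pattern, out$t2_motif) &&
    matchesProsite(out$t1_signature, out$t1_motif) &&
    matchesProsite(out$t2_signature, out$t2_motif) &&
    !matchesProsite(out$t1_signature, out$t2_motif) &&
    !matchesProsite(out$t2_signature, out$t1_motif)
  if (!ok)
    stop("packaged motif constants failed their self-consistency check",
         call. = FALSE)
  out
}
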