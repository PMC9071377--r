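# Rule-based classification of predicted DNA-binding ability from the bHLH
# basic region, following the classic basic-residue-count criteria:
# (1) fewer than `basic_min_count` basic residues in the basic region
#     -> non-binding;
# (2) otherwise E at E-2 and R at R-4 -> E-box binder, else non-E-box;
# (3) an E-box binder with H or K at H/K-1, E at E-2 and R at R-5 -> G-box,
#     otherwise E-box-non-G-box.
# A rule-bearing position gapped in the protein counts as a failed requirement.

#' The four binding categories
#' @return Character vector of category levels.
#' @export
binding_categories <- function() {
  c("NON_BINDING", "NON_EBOX", "GBOX", "EBOX_NON_GBOX")
}

#' Binding-rule parameters
#'
#' "More than five basic residues" is interpreted literally as a minimum count
#' of 6; both the residue set and the threshold are configurable.
#'
#' @param basic_residues Residues counted as basic.
#' @param basic_min_count Minimum basic-residue count for DNA binding.
#' @return Object of class `binding_rules`.
#' @export
binding_rules <- function(basic_residues = c("K", "R", "H"), basic_min_count = 6L) {
  if (basic_min_count < 1L) .stopf("basic_min_count must be >= 1")
  structure(list(basic_residues = basic_residues,
                 basic_min_count = as.integer(basic_min_count)),
            class = "binding_rules")
}

#' @noRd
.residue_at_column <- function(seq_chars, annotation, column) {
  pos <- annotation$column_map[column]
  if (is.na(pos)) NA_character_ else seq_chars[pos + 1L]
}

#' Classify predicted DNA-binding ability of an annotated domain
#'
#' @param protein The protein ([protein_record()] or string) the annotation
#'   was produced from.
#' @param annotation A `domain_annotation`; regions are computed on the fly if
#'   absent.
#' @param profile The profile defining regions and named positions.
#' @param rules A [binding_rules()] object.
#' @return One of [binding_categories()].
#' @export
classify_binding <- function(protein, annotation,
                             profile = default_domain_profile(),
                             rules = binding_rules()) {
  stopifnot(inherits(annotation, "domain_annotation"))
  seq <- if (inherits(protein, "protein_record")) protein$sequence else protein
  sv <- strsplit(seq, "")[[1]]
  basic_cols <- profile$region_spec$basic
  basic_pos <- annotation$column_map[basic_cols]
  basic_res <- sv[basic_pos[!is.na(basic_pos)] + 1L]
  n_basic <- sum(basic_res %in% rules$basic_residues)
  if (n_basic < rules$basic_min_count) return("NON_BINDING")
  np <- profile$named_positions
  at <- function(label) .residue_at_column(sv, annotation, np[[label]])
  ebox <- identical(at("E-2"), "E") && identical(at("R-4"), "R")
  if (!ebox) return("NON_EBOX")
  gbox <- at("H/K-1") %in% c("H", "K") && identical(at("E-2"), "E") &&
    identical(at("R-5"), "R")
  if (gbox) "GBOX" else "EBOX_NON_GBOX"
}

#' Count basic residues in the basic region of an annotated domain
#' @inheritParams classify_binding
#' @return Integer count.
#' @export
count_basic_residues <- function(protein, annotation,
                                 profile = default_domain_profile(),
                                 rules = binding_rules()) {
  seq <- if (inherits(protein, "protein_record")) protein$sequence else protein
  sv <- strsplit(seq, "")[[1]]
  basic_pos <- annotation$column_map[profile$region_spec$basic]
  basic_res <- sv[basic_pos[!is.na(basic_pos)] + 1L]
  sum(basic_res %in% rules$basic_residues)
}
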