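# Absolute quantification: mass <-> molecule conversions and the unit chain
# from fg/min per qRT/PCR reaction down to per-copy polymerase velocity.

# 5'-triphosphate ssRNA convention: sum of residue masses + 159.0 Da.
.rna_residue_da <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)
.rna_triphosphate_da <- 159.0

# unified atomic mass constant, grams per dalton
.dalton_g <- 1.66054e-24

#' Molecular weight of a single-stranded RNA
#'
#' Computes the molecular weight of an ssRNA from its sequence using the
#' 5'-triphosphate convention: the sum of the monophosphate residue masses
#' (A 329.21, U 306.17, C 305.18, G 345.21 Da) plus 159.0 Da for the
#' triphosphate 5' terminus. `T` is accepted and treated as `U`, so DNA-coded
#' template strings can be passed directly.
#'
#' @param sequence Non-empty character scalar over `A`, `C`, `G`, `U`
#'   (case-insensitive; `T` treated as `U`).
#' @return Molecular weight in kDa.
#' @examples
#' rna_molecular_weight("AUGC")
#' @export
rna_molecular_weight <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) {
    stop("sequence must be a non-empty RNA string", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars[chars == "T"] <- "U"
  bad <- which(!chars %in% names(.rna_residue_da))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d (alphabet A/C/G/U, T tolerated)",
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
  (sum(.rna_residue_da[chars]) + .rna_triphosphate_da) / 1000
}

#' Transcript specification
#'
#' A minimal description of an RNA species sufficient for mass/molecule
#' conversions: its length and molecular weight, optionally anchored to a
#' sequence. When a sequence is supplied it must match `length_nt` and its
#' computed molecular weight must agree with `mw_kda` to within 0.01 kDa.
#'
#' @param name Label.
#' @param length_nt Length in nucleotides (> 0).
#' @param mw_kda Molecular weight in kDa (> 0).
#' @param sequence Optional RNA sequence.
#' @return An object of class `transcript_spec`.
#' @export
transcript_spec <- function(name, length_nt, mw_kda, sequence = NULL) {
  stopifnot(length(length_nt) == 1L, length_nt > 0,
            length(mw_kda) == 1L, mw_kda > 0)
  if (!is.null(sequence)) {
    if (nchar(sequence) != length_nt) {
      stop("sequence length does not match length_nt", call. = FALSE)
    }
    mw_seq <- rna_molecular_weight(sequence)
    if (abs(mw_seq - mw_kda) > 0.01) {
      stop(sprintf("mw_kda (%.4f) disagrees with sequence-derived MW (%.4f kDa)",
                   mw_kda, mw_seq), call. = FALSE)
    }
  }
  structure(list(name = name, length_nt = as.numeric(length_nt),
                 mw_kda = as.numeric(mw_kda), sequence = sequence),
            class = "transcript_spec")
}

#' Default minigene transcript specifications
#'
#' The SOD1 minigene pre-mRNA (567 nt, 168.14 kDa) and spliced mRNA (304 nt).
#' The spliced species' molecular weight is an equal-base-composition estimate
#' (the sequence is not published); the pre-mRNA value is the reporter
#' system's configured constant.
#'
#' @return Named list with elements `pre_mrna` and `spliced_mrna`.
#' @export
minigene_transcripts <- function() {
  list(
    pre_mrna = transcript_spec("SOD1-minigene-pre-mRNA", 567, 168.14),
    # 304 nt at the mean residue mass (321.44 Da) + 159 Da terminus
    spliced_mrna = transcript_spec("SOD1-minigene-spliced-mRNA", 304, 97.88)
  )
}

#' Cell line configuration
#'
#' @param name Label.
#' @param copy_number Integrated minigene copies per cell (>= 1).
#' @param splice_competent Logical; FALSE for the splice-defective mutant.
#' @param rnaseh1_level RNase H1 activity scaling rho (>= 0, 1 = wild type).
#' @return An object of class `cell_line_config`.
#' @export
cell_line_config <- function(name, copy_number, splice_competent = TRUE,
                             rnaseh1_level = 1) {
  stopifnot(copy_number >= 1, copy_number == as.integer(copy_number),
            rnaseh1_level >= 0)
  structure(list(name = name, copy_number = as.integer(copy_number),
                 splice_competent = isTRUE(splice_competent),
                 rnaseh1_level = as.numeric(rnaseh1_level)),
            class = "cell_line_config")
}

#' Default minigene cell lines
#'
#' `SOD187M/TO`: splice-defective line, 6 integrated copies (nuclear
#' compartment readout). `SOD/TO`: splice-competent line, 9 copies
#' (cytoplasmic readout).
#'
#' @return Named list of [cell_line_config()] objects.
#' @export
minigene_cell_lines <- function() {
  list(
    SOD187M_TO = cell_line_config("SOD187M/TO", 6, splice_competent = FALSE),
    SOD_TO = cell_line_config("SOD/TO", 9, splice_competent = TRUE)
  )
}

#' Convert a per-reaction mass rate to a per-cell rate
#'
#' A qRT/PCR reaction receives total RNA from `cells_per_reaction` cells
#' (default 1000, i.e. one tenth of a 10,000-cell well), so an accumulation
#' slope in fg/min per reaction converts to ag/min/cell by
#' `x * 1000 / cells_per_reaction` (fg -> ag is a factor of 1000).
#'
#' @param rate_fg_per_min Slope in fg/min per reaction (may be a vector).
#' @param cells_per_reaction Cells contributing RNA to one reaction (>= 1).
#' @return Rate(s) in ag/min/cell.
#' @examples
#' per_cell_rate(16.7, 1000)  # 16.7 ag/min/cell
#' @export
per_cell_rate <- function(rate_fg_per_min, cells_per_reaction = 1000) {
  if (length(cells_per_reaction) != 1L || !is.finite(cells_per_reaction) ||
      cells_per_reaction < 1) {
    stop("cells_per_reaction must be a single count >= 1", call. = FALSE)
  }
  rate_fg_per_min * 1000 / cells_per_reaction
}

#' Convert a per-cell mass rate to molecules per minute
#'
#' The mass of one molecule is `mw_kda * 1000 * 1.66054e-24` g (unified
#' atomic mass constant), so an accumulation rate of `r` ag/min/cell
#' corresponds to `r * 1e-18 / m` molecules/min/cell.
#'
#' @param rate_ag_per_min_cell Rate in ag/min/cell.
#' @param transcript A [transcript_spec()].
#' @return Molecules per minute per cell.
#' @examples
#' tx <- minigene_transcripts()$pre_mrna
#' molecules_per_minute(16.7, tx)  # ~59.8
#' @export
molecules_per_minute <- function(rate_ag_per_min_cell, transcript) {
  stopifnot(inherits(transcript, "transcript_spec"))
  molecule_g <- transcript$mw_kda * 1000 * .dalton_g
  rate_ag_per_min_cell * 1e-18 / molecule_g
}

#' Polymerase velocity implied by a molecule synthesis rate
#'
#' Converts molecules/min/cell into total nucleotides polymerised per minute
#' (kb/min over all gene copies) and, divided by the copy number, the
#' per-copy RNA polymerase II velocity.
#'
#' @param molecules_per_min Molecules synthesised per minute per cell.
#' @param transcript A [transcript_spec()].
#' @param copy_number Integrated gene copies per cell (>= 1).
#' @return List with `total_kb_per_min` and `per_copy_kb_per_min`.
#' @examples
#' tx <- minigene_transcripts()$pre_mrna
#' polymerase_rate(60, tx, 6)  # 34 kb/min total, ~5.7 kb/min per copy
#' @export
polymerase_rate <- function(molecules_per_min, transcript, copy_number) {
  stopifnot(inherits(transcript, "transcript_spec"))
  if (length(copy_number) != 1L || copy_number < 1) {
    stop("copy_number must be >= 1", call. = FALSE)
  }
  total <- molecules_per_min * transcript$length_nt / 1000
  list(total_kb_per_min = total, per_copy_kb_per_min = total / copy_number)
}

#' Per-gene-copy mass rate
#'
#' @param rate_ag_per_min_cell Rate in ag/min/cell.
#' @param copy_number Gene copies per cell (>= 1).
#' @return Rate in ag/min/copy/cell.
#' @examples
#' per_copy_rate(16.7, 6)  # 2.78 ag/min/copy/cell
#' @export
per_copy_rate <- function(rate_ag_per_min_cell, copy_number) {
  if (length(copy_number) != 1L || copy_number < 1) {
    stop("copy_number must be >= 1", call. = FALSE)
  }
  rate_ag_per_min_cell / copy_number
}

#' Put an accumulation rate on a common cross-cell-line basis
#'
#' Rescales an observed accumulation rate by a transcript length ratio and a
#' copy-number ratio so rates measured in different cell lines (different
#' species lengths, different integrated copy numbers) can be compared on a
#' common per-cell basis. The result is simply the product of the three
#' operands; the ratios are explicit arguments rather than derived internally
#' so that a reported comparison can be reproduced verbatim.
#'
#' @param observed_rate Rate in ag/min/cell.
#' @param length_ratio Length correction factor (> 0).
#' @param copy_ratio Copy-number correction factor (> 0).
#' @return Corrected rate in ag/min/cell.
#' @examples
#' reconcile_accumulation(17.6, 0.6, 1.5)  # 15.8
#' @export
reconcile_accumulation <- function(observed_rate, length_ratio, copy_ratio) {
  if (!is.finite(length_ratio) || length_ratio <= 0 ||
      !is.finite(copy_ratio) || copy_ratio <= 0) {
    stop("length_ratio and copy_ratio must be positive", call. = FALSE)
  }
  observed_rate * length_ratio * copy_ratio
}

#' Round to a number of significant figures
#' @noRd
.signif_chr <- function(x, digits) signif(x, digits)

#' Conversion-chain report for an accumulation slope
#'
#' Runs the full unit-conversion chain for a measured accumulation slope and
#' returns both raw and conventionally rounded values: ag/min/cell (3
#' significant figures), molecules/min (nearest ten), total polymerase rate
#' (nearest integer kb/min), per-copy polymerase rate (1 decimal kb/min) and
#' the per-copy mass rate (3 significant figures ag/min/copy/cell). The
#' roundings are presentation conventions applied here only; the numeric
#' operations themselves are never rounded.
#'
#' @param slope_fg_per_min Measured slope, fg/min per reaction.
#' @param transcript A [transcript_spec()].
#' @param copy_number Gene copies per cell.
#' @param cells_per_reaction Cells per qRT/PCR reaction (default 1000).
#' @return A one-row [tibble::tibble()] with raw and `_rounded` columns.
#' @examples
#' report_conversion_chain(16.7, minigene_transcripts()$pre_mrna, 6)
#' @export
report_conversion_chain <- function(slope_fg_per_min, transcript, copy_number,
                                    cells_per_reaction = 1000) {
  ag_cell <- per_cell_rate(slope_fg_per_min, cells_per_reaction)
  mol_min <- molecules_per_minute(ag_cell, transcript)
  pol <- polymerase_rate(mol_min, transcript, copy_number)
  ag_copy <- per_copy_rate(ag_cell, copy_number)
  tibble::tibble(
    slope_fg_per_min = slope_fg_per_min,
    ag_per_min_cell = ag_cell,
    ag_per_min_cell_rounded = signif(ag_cell, 3),
    molecules_per_min = mol_min,
    molecules_per_min_rounded = round(mol_min / 10) * 10,
    total_kb_per_min = pol$total_kb_per_min,
    total_kb_per_min_rounded = round(pol$total_kb_per_min),
    per_copy_kb_per_min = pol$per_copy_kb_per_min,
    per_copy_kb_per_min_rounded = round(pol$per_copy_kb_per_min, 1),
    ag_per_min_copy_cell = ag_copy,
    ag_per_min_copy_cell_rounded = signif(ag_copy, 3)
  )
}
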