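#' Five-level affinity grading
#'
#' Discretizes an affinity on the negative log10 molar scale (pIC50, pKi or
#' pKd) into the five relevance grades used as ranking labels: grade 0 for
#' values below 6, then one grade per unit up to grade 4 for values of 9 or
#' more. Intervals are left-closed, so a boundary value maps to the higher
#' grade (\code{gradeAffinity(7) == 2}).
#'
#' @param value numeric vector of affinities (-log10 molar). Must be finite.
#' @return integer vector of grades in 0..4.
#' @examples
#' gradeAffinity(c(5.999, 6, 6.5, 7, 9.2))  # 0 1 1 2 4
#' @export
gradeAffinity <- function(value) {
  if (!is.numeric(value) || length(value) == 0L)
    stop("'value' must be a non-empty numeric vector")
  if (!all(is.finite(value))) stop("affinity values must be finite")
  as.integer(findInterval(value, c(6, 7, 8, 9)))
}

#' Binary activity label
#'
#' A compound is called active when its affinity reaches 6 on the -log10
#' molar scale (e.g. pIC50 >= 6, i.e. IC50 <= 1 uM), the conventional
#' activity cutoff in ligand-based screening.
#'
#' @param value numeric vector of affinities (-log10 molar). Must be finite.
#' @return logical vector.
#' @export
labelActive <- function(value) {
  if (!is.numeric(value) || length(value) == 0L)
    stop("'value' must be a non-empty numeric vector")
  if (!all(is.finite(value))) stop("affinity values must be finite")
  value >= 6
}

#' Validate (or repair) amino-acid sequences
#'
#' Sequences must be non-empty and drawn from the 20 canonical amino-acid
#' letters; the CTD property groups are defined only for those. Non-canonical
#' letters (B, J, O, U, X, Z, ...) are rejected by default, or mapped to a
#' surrogate residue when \code{nonCanonical = "map"}.
#'
#' @param sequences character vector; lowercase is accepted and uppercased.
#' @param nonCanonical \code{"error"} (default) or \code{"map"}.
#' @param surrogate single canonical letter used when mapping.
#' @return character vector of validated, uppercased sequences.
#' @export
validateSequences <- function(sequences, nonCanonical = c("error", "map"),
                              surrogate = "A") {
  nonCanonical <- match.arg(nonCanonical)
  if (!is.character(sequences)) stop("'sequences' must be character")
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) stop("empty sequence")
  bad <- grepl(sprintf("[^%s]", paste(.AA20, collapse = "")), sequences)
  if (any(bad)) {
    if (nonCanonical == "error")
      stop("non-canonical amino-acid letters in sequence(s): ",
           paste(which(bad), collapse = ", "))
    if (!surrogate %in% .AA20) stop("surrogate must be a canonical residue")
    sequences[bad] <- gsub(sprintf("[^%s]", paste(.AA20, collapse = "")),
                           surrogate, sequences[bad])
  }
  sequences
}

#' Construct a validated RankingDataset
#'
#' Assembles targets, compounds (with their descriptor matrix) and affinity
#' records into a \linkS4class{RankingDataset}. Grades are (re)derived from
#' the affinity values via [gradeAffinity()] unless already supplied.
#' Duplicate (target, compound) affinity rows are collapsed keeping the
#' first occurrence, with a warning.
#'
#' @param targets data.frame with \code{target_id}, \code{sequence} and
#'   optionally \code{family}.
#' @param compounds data.frame with \code{compound_id} and optionally
#'   \code{smiles}.
#' @param descriptors numeric matrix, one row per compound in the same
#'   order; rownames are set to the compound ids.
#' @param affinities data.frame with \code{target_id}, \code{compound_id},
#'   \code{measurement} (pIC50/pKi/pKd) and \code{value}.
#' @param descriptorDim expected descriptor length (default 32).
#' @param nonCanonical,surrogate sequence policy, see [validateSequences()].
#' @return a \linkS4class{RankingDataset}.
#' @export
RankingDataset <- function(targets, compounds, descriptors, affinities,
                           descriptorDim = 32L,
                           nonCanonical = c("error", "map"), surrogate = "A") {
  targets <- as.data.frame(targets)
  compounds <- as.data.frame(compounds)
  affinities <- as.data.frame(affinities)
  if (is.null(targets$family)) targets$family <- NA_character_
  if (is.null(compounds$smiles)) compounds$smiles <- NA_character_
  targets$sequence <- validateSequences(targets$sequence, nonCanonical,
                                        surrogate)
  descriptors <- as.matrix(descriptors)
  storage.mode(descriptors) <- "double"
  if (ncol(descriptors) != descriptorDim)
    stop(sprintf("descriptor matrix has %d columns, expected %d",
                 ncol(descriptors), descriptorDim))
  rownames(descriptors) <- compounds$compound_id
  if (nrow(affinities)) {
    key <- paste(affinities$target_id, affinities$compound_id, sep = "\r")
    if (anyDuplicated(key)) {
      warning(sum(duplicated(key)),
              " duplicate (target, compound) affinity rows dropped (kept first)")
      affinities <- affinities[!duplicated(key), , drop = FALSE]
    }
    affinities$grade <- gradeAffinity(affinities$value)
    rownames(affinities) <- NULL
  } else {
    affinities$grade <- integer()
  }
  new("RankingDataset", targets = targets, compounds = compounds,
      descriptors = descriptors, descriptorDim = as.integer(descriptorDim),
      affinities = affinities)
}

#' Curation rules for benchmark assembly
#'
#' Mirrors the filters used to curate per-target ligand sets from public
#' binding databases: an optional window on the number of non-redundant
#' ligands per target, removal of targets whose ligands cover only the two
#' lowest grades, and removal of targets whose highest observed grade holds
#' less than a minimum fraction of the records. No ligand-count window is
#' enforced by default.
#'
#' @param minLigands,maxLigands optional integer bounds on ligands/target.
#' @param dropLowGradeOnly drop targets whose grades are a subset of {0, 1}.
#' @param minTopGradeFrac minimum fraction of records at the target's
#'   highest observed grade (default 0.05).
#' @return a list of class \code{curationRules}.
#' @export
curationRules <- function(minLigands = NA_integer_, maxLigands = NA_integer_,
                          dropLowGradeOnly = TRUE, minTopGradeFrac = 0.05) {
  structure(list(minLigands = minLigands, maxLigands = maxLigands,
                 dropLowGradeOnly = dropLowGradeOnly,
                 minTopGradeFrac = minTopGradeFrac),
            class = "curationRules")
}

#' Apply benchmark curation filters
#'
#' Collapses redundant (target, compound) records keeping the first
#' occurrence, then drops every target that fails any configured rule of
#' [curationRules()]. Targets and compounds no longer referenced by any
#' affinity are removed. The operation is idempotent.
#'
#' @param dataset a \linkS4class{RankingDataset}.
#' @param rules a [curationRules()] object.
#' @return the filtered \linkS4class{RankingDataset}.
#' @export
applyCurationFilters <- function(dataset, rules = curationRules()) {
  stopifnot(is(dataset, "RankingDataset"), inherits(rules, "curationRules"))
  af <- dataset@affinities
  if (!nrow(af)) {
    warning("empty dataset: nothing to curate")
    return(dataset)
  }
  keep <- vapply(split(af$grade, af$target_id), function(g) {
    n <- length(g)
    if (!is.na(rules$minLigands) && n < rules$minLigands) return(FALSE)
    if (!is.na(rules$maxLigands) && n > rules$maxLigands) return(FALSE)
    if (rules$dropLowGradeOnly && all(g <= 1L)) return(FALSE)
    if (mean(g == max(g)) < rules$minTopGradeFrac) return(FALSE)
    TRUE
  }, logical(1))
  keepTargets <- names(keep)[keep]
  af <- af[af$target_id %in% keepTargets, , drop = FALSE]
  tg <- dataset@targets[dataset@targets$target_id %in% keepTargets, ,
                        drop = FALSE]
  keepComp <- dataset@compounds$compound_id %in% unique(af$compound_id)
  cp <- dataset@compounds[keepComp, , drop = FALSE]
  ds <- dataset@descriptors[keepComp, , drop = FALSE]
  rownames(af) <- NULL; rownames(tg) <- NULL; rownames(cp) <- NULL
  new("RankingDataset", targets = tg, compounds = cp, descriptors = ds,
      descriptorDim = dataset@descriptorDim, affinities = af)
}

#' Harmonize relevance labels across measurement platforms
#'
#' Regrades every affinity on its own target's measurement scale so that
#' grades are comparable *within* each target even when different targets
#' were assayed on different platforms (pIC50 vs pKi vs pKd). No cross-target
#' value comparison is performed: pair-wise rankers only ever compare labels
#' within one query, which is what makes heterogeneous training data usable.
#' A target mixing measurement types is rejected as its within-target
#' ordering would be ambiguous.
#'
#' @param dataset a \linkS4class{RankingDataset}.
#' @return the dataset with grades re-derived per target.
#' @export
harmonizeLabels <- function(dataset) {
  stopifnot(is(dataset, "RankingDataset"))
  af <- dataset@affinities
  if (!nrow(af)) return(dataset)
  mixed <- tapply(af$measurement, af$target_id,
                  function(m) length(unique(m)) > 1L)
  if (any(mixed))
    stop("mixed measurement types within target(s): ",
         paste(names(mixed)[mixed], collapse = ", "))
  af$grade <- gradeAffinity(af$value)
  methods::initialize(dataset, affinities = af)
}
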