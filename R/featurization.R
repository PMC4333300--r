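# Target and compound featurization, and the two pair-feature mappings.

.pkgEnv <- new.env(parent = emptyenv())

#' CTD property group tables
#'
#' The seven physicochemical properties (hydrophobicity, normalized van der
#' Waals volume, polarity, polarizability, charge, secondary-structure
#' propensity, solvent accessibility), each partitioning the 20 canonical
#' residues into three groups. Shipped as a plain CSV under
#' \code{inst/extdata/ctd_property_groups.csv} so the grouping is auditable.
#'
#' @return data.frame with columns property, group, group_label, residues.
#' @export
ctdPropertyGroups <- function() {
  if (is.null(.pkgEnv$ctdGroups)) {
    path <- system.file("extdata", "ctd_property_groups.csv",
                        package = "RankVS", mustWork = TRUE)
    .pkgEnv$ctdGroups <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .pkgEnv$ctdGroups
}

# per-property integer lookup: named int vector residue -> group 1..3
.ctdLookup <- function() {
  if (is.null(.pkgEnv$ctdLookup)) {
    gr <- ctdPropertyGroups()
    props <- unique(gr$property)
    .pkgEnv$ctdLookup <- lapply(stats::setNames(props, props), function(p) {
      sub <- gr[gr$property == p, ]
      map <- integer(0)
      for (i in seq_len(nrow(sub))) {
        res <- strsplit(sub$residues[i], "")[[1]]
        map[res] <- sub$group[i]
      }
      map[.AA20]
    })
  }
  .pkgEnv$ctdLookup
}

#' Composition/Transition/Distribution protein descriptors
#'
#' Computes the 147-dimensional CTD representation of a protein sequence:
#' for each of 7 physicochemical properties the 20 residues fall into 3
#' groups, and the sequence is summarized by 3 Composition values (fraction
#' of residues per group), 3 Transition values (frequency of adjacent
#' residue pairs switching between the 3 unordered group pairs, divided by
#' L-1) and 15 Distribution values (for each group, the 1-based positions of
#' its first, 25th-, 50th-, 75th- and 100th-percentile occurrences, divided
#' by L and expressed as percentages; all 0 for an absent group).
#' 7 x (3 + 3 + 15) = 147 values in a fixed, named order.
#'
#' The percentile occurrence index for a group with N occurrences is
#' \code{max(1, ceiling(p * N))} for p in 0.25/0.5/0.75/1, and 1 for the
#' "first" statistic.
#'
#' @param sequence a single amino-acid string, length >= 2, canonical
#'   residues only (see [validateSequences()]).
#' @return named numeric vector of length 147.
#' @examples
#' length(ctdFeatures("MKVLAARG"))  # 147
#' @export
ctdFeatures <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- validateSequences(sequence)
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  if (L < 2L) stop("sequence must have length >= 2")
  lookups <- .ctdLookup()
  out <- numeric(0)
  for (p in names(lookups)) {
    g <- unname(lookups[[p]][res])            # group index per residue
    comp <- tabulate(g, nbins = 3L) / L
    a <- g[-L]; b <- g[-1L]
    lo <- pmin(a, b); hi <- pmax(a, b)
    trans <- c(sum(lo == 1L & hi == 2L),
               sum(lo == 1L & hi == 3L),
               sum(lo == 2L & hi == 3L)) / (L - 1L)
    distr <- unlist(lapply(1:3, function(k) {
      pos <- which(g == k)
      n <- length(pos)
      if (!n) return(numeric(5))
      idx <- c(1L, pmax(1L, ceiling(c(0.25, 0.5, 0.75, 1) * n)))
      pos[idx] / L * 100
    }))
    v <- c(comp, trans, distr)
    names(v) <- paste0(p, ".", c("C.g1", "C.g2", "C.g3",
                                 "T.g12", "T.g13", "T.g23",
                                 t(outer(paste0("D.g", 1:3),
                                         c("first", "p25", "p50", "p75", "p100"),
                                         paste, sep = "."))))
    out <- c(out, v)
  }
  out
}

#' Compound descriptors (32-dimensional)
#'
#' Returns the fixed-length compound descriptor vector. A precomputed
#' numeric vector of the configured length passes through unchanged; a
#' SMILES string is featurized with the built-in open descriptor set
#' (requires the ChemmineR and ChemmineOB packages): molecular weight, logP,
#' molar refractivity, topological polar surface area, hydrogen-bond
#' acceptor/donor counts, Gasteiger partial-charge statistics, and
#' constitutional counts (atoms, bonds, element counts, ring statistics),
#' padded with simple derived ratios to 32 entries. The descriptor names
#' are returned on the vector.
#'
#' @param x numeric vector of length \code{dim}, or a single SMILES string.
#' @param dim expected descriptor length (default 32).
#' @return named numeric vector of length \code{dim}.
#' @export
compoundDescriptors <- function(x, dim = 32L) {
  if (is.numeric(x)) {
    if (length(x) != dim)
      stop(sprintf("precomputed descriptor has length %d, expected %d",
                   length(x), dim))
    if (!all(is.finite(x))) stop("non-finite descriptor entries")
    return(x)
  }
  if (!is.character(x) || length(x) != 1L)
    stop("'x' must be a numeric descriptor vector or a single SMILES string")
  if (dim != 32L)
    stop("the built-in SMILES descriptor set has exactly 32 entries")
  .smilesDescriptors(x)
}

.smilesDescriptors <- function(smiles) {
  for (pkg in c("ChemmineR", "ChemmineOB"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("SMILES featurization requires the ", pkg, " package")
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  if (is.null(sdf) || !length(sdf)) stop("unparseable SMILES: ", smiles)
  p <- ChemmineR::propOB(sdf)
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  elem <- gsub("_.*", "", rownames(ab))
  nHeavy <- sum(elem != "H")
  nBonds <- if (is.null(dim(bb))) 0L else nrow(bb)
  orders <- if (nBonds) bb[, 3] else integer(0)
  rings <- tryCatch(ChemmineR::rings(sdf[[1]]), error = function(e) list())
  nRings <- length(rings)
  ringAtoms <- if (nRings) length(unique(unlist(rings))) else 0
  maxRing <- if (nRings) max(lengths(rings)) else 0
  # Gasteiger partial charges via a MOL2 conversion
  q <- tryCatch({
    m2 <- ChemmineOB::convertFormat("SMI", "MOL2", paste0(smiles, " x\n"))
    ln <- strsplit(m2, "\n")[[1]]
    i1 <- grep("@<TRIPOS>ATOM", ln, fixed = TRUE)[1] + 1L
    i2 <- grep("@<TRIPOS>BOND", ln, fixed = TRUE)[1] - 1L
    vapply(strsplit(trimws(ln[i1:i2]), "\\s+"),
           function(f) as.numeric(f[9]), numeric(1))
  }, error = function(e) numeric(0))
  if (!length(q) || any(!is.finite(q))) q <- 0
  cnt <- function(e) sum(elem %in% e)
  nHal <- cnt(c("F", "Cl", "Br", "I"))
  nFormula <- function(sym) {  # H count from the molecular formula
    m <- regmatches(p$formula, regexec(paste0(sym, "([0-9]*)"), p$formula))[[1]]
    if (length(m) < 2 || !nzchar(m[1])) 0
    else if (!nzchar(m[2])) 1 else as.numeric(m[2])
  }
  nH <- nFormula("H")
  v <- c(MW = p$MW, logP = p$logP, MR = p$MR, TPSA = p$TPSA,
         HBA1 = p$HBA1, HBA2 = p$HBA2, HBD = p$HBD, nF = p$nF,
         sumPosCharge = sum(q[q > 0]), sumNegCharge = sum(q[q < 0]),
         maxAbsCharge = max(abs(q)), meanAbsCharge = mean(abs(q)),
         netCharge = round(sum(q)),
         nHeavyAtoms = nHeavy, nBonds = nBonds, nH = nH,
         nC = cnt("C"), nN = cnt("N"), nO = cnt("O"), nS = cnt("S"),
         nP = cnt("P"), nHalogen = nHal,
         nSingleBonds = sum(orders == 1), nDoubleBonds = sum(orders == 2),
         nTripleBonds = sum(orders == 3),
         nRings = nRings, nRingAtoms = ringAtoms, maxRingSize = maxRing,
         fracC = cnt("C") / max(1, nHeavy),
         fracHetero = 1 - cnt("C") / max(1, nHeavy),
         bondAtomRatio = nBonds / max(1, nHeavy),
         meanAtomicMass = p$MW / max(1, nHeavy + nH))
  v <- vapply(v, as.numeric, numeric(1))
  if (!all(is.finite(v))) stop("non-finite descriptor computed for ", smiles)
  stopifnot(length(v) == 32L)
  v
}

#' Side-by-side (concatenation) pair-feature mapping
#'
#' Maps a target feature vector and a compound descriptor vector to the
#' pair-feature vector used by the cross-target strategies: the target
#' vector followed by the compound vector. With the default 147-dim CTD and
#' 32-dim compound descriptors the result has 179 entries.
#'
#' @param tVec numeric target feature vector.
#' @param cVec numeric compound descriptor vector.
#' @return numeric vector of length \code{length(tVec) + length(cVec)}.
#' @export
mapConcat <- function(tVec, cVec) {
  stopifnot(is.numeric(tVec), is.numeric(cVec),
            length(tVec) > 0L, length(cVec) > 0L)
  if (!all(is.finite(tVec)) || !all(is.finite(cVec)))
    stop("non-finite feature entries")
  c(unname(tVec), unname(cVec))
}

#' Kronecker cross-term pair-feature mapping
#'
#' Maps a target and a compound vector to their Kronecker product, encoding
#' every multiplicative target-compound feature interaction: entry
#' (i*|c| + j) equals \code{tVec[i] * cVec[j]} (target-major order). With
#' the default dimensions the result has 147 x 32 = 4704 entries. A linear
#' scorer on this representation is exactly a bilinear scorer on the
#' original (target, compound) pair, which is what lets a single linear
#' ranking model express target-specific compound preferences.
#'
#' @inheritParams mapConcat
#' @return numeric vector of length \code{length(tVec) * length(cVec)}.
#' @export
mapCrossTerm <- function(tVec, cVec) {
  stopifnot(is.numeric(tVec), is.numeric(cVec),
            length(tVec) > 0L, length(cVec) > 0L)
  if (!all(is.finite(tVec)) || !all(is.finite(cVec)))
    stop("non-finite feature entries")
  as.numeric(kronecker(unname(tVec), unname(cVec)))
}

#' Fit a column-standardization transform
#'
#' Centers each column to mean 0 and scales it to unit (population)
#' standard deviation, so the two-point column [1, 3] maps to [-1, 1];
#' zero-variance columns are centered and left unscaled (all 0 after the
#' transform). The returned transform is meant to be fitted on training
#' rows only and re-applied verbatim to test rows via [applyTransform()].
#'
#' @param X numeric matrix with at least 2 rows.
#' @return an object of class \code{featureTransform} with elements
#'   \code{center}, \code{scale} and \code{scaled} (the transformed input).
#' @export
standardizeFeatures <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("standardization needs at least 2 rows")
  ctr <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, ctr, "-")^2))
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  tr <- structure(list(center = ctr, scale = sdv), class = "featureTransform")
  tr$scaled <- applyTransform(tr, X)
  tr
}

#' Apply a fitted standardization transform
#'
#' @param transform a \code{featureTransform} from [standardizeFeatures()].
#' @param X numeric matrix with the same number of columns.
#' @return the transformed matrix.
#' @export
applyTransform <- function(transform, X) {
  stopifnot(inherits(transform, "featureTransform"))
  X <- as.matrix(X)
  if (ncol(X) != length(transform$center))
    stop("column count does not match the fitted transform")
  sweep(sweep(X, 2L, transform$center, "-"), 2L, transform$scale, "/")
}
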