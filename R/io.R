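# File readers/writers and the run manifest.

#' Read protein targets from FASTA
#'
#' One record per FASTA entry; the target id is the first
#' whitespace-delimited token of the header, sequences are uppercased and
#' validated against the canonical-residue policy.
#'
#' @param path FASTA file.
#' @param nonCanonical,surrogate see [validateSequences()].
#' @return data.frame with columns \code{target_id}, \code{sequence}.
#' @export
readFastaTargets <- function(path, nonCanonical = c("error", "map"),
                             surrogate = "A") {
  ss <- Biostrings::readAAStringSet(path)
  if (!length(ss)) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- validateSequences(as.character(ss), nonCanonical, surrogate)
  data.frame(target_id = ids, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein targets to FASTA
#'
#' @param targets data.frame with \code{target_id} and \code{sequence}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeFastaTargets <- function(targets, path) {
  ss <- Biostrings::AAStringSet(stats::setNames(targets$sequence,
                                                targets$target_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

.readDelim <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE)
}

#' Read a target-compound affinity table
#'
#' CSV (or TSV, by extension) with a required header row and columns
#' \code{target_id}, \code{compound_id}, \code{measurement}
#' (pIC50/pKi/pKd) and \code{value}. Well-formed rows are parsed and
#' graded with [gradeAffinity()]; malformed rows (non-numeric or
#' non-finite value, unknown measurement) are collected into an error
#' report attached as \code{attr(, "errors")}, with a warning.
#'
#' @param path input file.
#' @return data.frame of affinity records with a \code{grade} column;
#'   attribute \code{errors} holds a data.frame (line, reason) of rejected
#'   rows.
#' @export
readAffinityTable <- function(path) {
  raw <- .readDelim(path)
  need <- c("target_id", "compound_id", "measurement", "value")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- !is.finite(value) | !(raw$measurement %in% .MEASUREMENTS)
  errors <- data.frame(line = which(bad) + 1L,
                       reason = ifelse(!is.finite(value[bad]) |
                                         is.na(value[bad]),
                                       "non-numeric value",
                                       "unknown measurement")[seq_len(sum(bad))])
  if (any(bad))
    warning(sum(bad), " malformed row(s) rejected (see attr(,'errors'))")
  out <- data.frame(target_id = raw$target_id[!bad],
                    compound_id = raw$compound_id[!bad],
                    measurement = raw$measurement[!bad],
                    value = value[!bad],
                    stringsAsFactors = FALSE)
  out$grade <- if (nrow(out)) gradeAffinity(out$value) else integer()
  attr(out, "errors") <- errors
  out
}

#' Write an affinity table
#'
#' @param affinities data.frame of affinity records.
#' @param path output CSV.
#' @return invisibly, \code{path}.
#' @export
writeAffinityTable <- function(affinities, path) {
  utils::write.csv(affinities[c("target_id", "compound_id", "measurement",
                                "value")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write a compound descriptor table
#'
#' CSV with a \code{compound_id} column followed by the numeric descriptor
#' columns (32 for the built-in set).
#'
#' @param path file path.
#' @param dim expected descriptor length.
#' @return \code{readDescriptorTable}: numeric matrix with compound ids as
#'   rownames.
#' @export
readDescriptorTable <- function(path, dim = 32L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"compound_id" %in% names(df)) stop("missing column compound_id")
  M <- as.matrix(df[setdiff(names(df), "compound_id")])
  storage.mode(M) <- "double"
  if (ncol(M) != dim)
    stop(sprintf("descriptor table has %d columns, expected %d", ncol(M), dim))
  if (!all(is.finite(M))) stop("non-finite descriptor entries")
  rownames(M) <- df$compound_id
  M
}

#' @rdname readDescriptorTable
#' @param descriptors numeric matrix with compound ids as rownames.
#' @export
writeDescriptorTable <- function(descriptors, path) {
  df <- data.frame(compound_id = rownames(descriptors),
                   descriptors, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every run of the pipeline records what produced its outputs: a command
#' label, the configuration, the master seed, md5 digests of the input
#' files, the package version and a timestamp.
#'
#' @param path output JSON file.
#' @param command free-text command label.
#' @param config configuration list (serialized as-is).
#' @param seed master seed of the run.
#' @param inputPaths character vector of input files to digest.
#' @return invisibly, \code{path}.
#' @export
writeRunManifest <- function(path, command, config = list(), seed = NA,
                             inputPaths = character()) {
  digests <- if (length(inputPaths))
    as.list(tools::md5sum(inputPaths)) else list()
  cfg <- config
  cfg$familyMap <- NULL              # potentially large; inputs carry it
  jsonlite::write_json(
    list(command = command, seed = seed,
         config = cfg[!vapply(cfg, is.null, logical(1))],
         input_digests = digests,
         package_version = as.character(utils::packageVersion("RankVS")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a RankingDataset to plain-text files
#'
#' Emits \code{targets.fasta}, \code{compounds.csv} (descriptor table),
#' \code{affinities.csv} and, when families are annotated,
#' \code{families.csv} into \code{dir}. [readRankingDataset()] round-trips
#' them.
#'
#' @param dataset a \linkS4class{RankingDataset}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeRankingDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "RankingDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFastaTargets(dataset@targets, file.path(dir, "targets.fasta"))
  writeDescriptorTable(dataset@descriptors, file.path(dir, "compounds.csv"))
  writeAffinityTable(dataset@affinities, file.path(dir, "affinities.csv"))
  if (!all(is.na(dataset@targets$family)))
    utils::write.csv(dataset@targets[c("target_id", "family")],
                     file.path(dir, "families.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeRankingDataset
#' @param descriptorDim expected descriptor length (default 32).
#' @export
readRankingDataset <- function(dir, descriptorDim = 32L) {
  tg <- readFastaTargets(file.path(dir, "targets.fasta"))
  famPath <- file.path(dir, "families.csv")
  if (file.exists(famPath)) {
    fam <- utils::read.csv(famPath, stringsAsFactors = FALSE)
    tg$family <- fam$family[match(tg$target_id, fam$target_id)]
  }
  D <- readDescriptorTable(file.path(dir, "compounds.csv"), descriptorDim)
  af <- readAffinityTable(file.path(dir, "affinities.csv"))
  RankingDataset(tg, data.frame(compound_id = rownames(D),
                                stringsAsFactors = FALSE),
                 D, af, descriptorDim = descriptorDim)
}
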