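#' Write genotypes in GenePop format
#'
#' Two-digit allele coding, one population block, individual ids as sample
#' names. Missing genotypes are written as `0000`.
#'
#' @param genotypes a [genotypeTable].
#' @param path output file.
#' @param title header line.
#' @export
writeGenePop <- function(genotypes, path, title = "nestshare genotypes") {
  a1 <- genotypes$a1; a2 <- genotypes$a2
  code <- function(x) ifelse(is.na(x), "00", sprintf("%02d", x))
  rows <- vapply(seq_len(nrow(a1)), function(i)
    paste0(rownames(a1)[i], " ,  ",
           paste0(code(a1[i, ]), code(a2[i, ]), collapse = " ")),
    character(1))
  writeLines(c(title, colnames(a1), "POP", rows), path)
}

#' Read genotypes from a GenePop file
#'
#' Supports the common single-population layout with 2- or 3-digit allele
#' codes and loci listed one per line or comma-separated.
#'
#' @param path GenePop file.
#' @return a [genotypeTable].
#' @export
readGenePop <- function(path) {
  ln <- trimws(readLines(path))
  popAt <- which(toupper(ln) == "POP")[1]
  if (is.na(popAt)) stop("no POP line: not a GenePop file")
  loci <- ln[2:(popAt - 1L)]
  if (length(loci) == 1L && grepl(",", loci))
    loci <- trimws(strsplit(loci, ",")[[1]])
  body <- ln[(popAt + 1L):length(ln)]
  body <- body[nzchar(body) & toupper(body) != "POP"]
  ids <- character(length(body))
  a1 <- matrix(NA_integer_, length(body), length(loci),
               dimnames = list(NULL, loci))
  a2 <- a1
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], ",")[[1]]
    ids[i] <- trimws(parts[1])
    gen <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(gen) != length(loci))
      stop("genotype count mismatch for individual ", ids[i])
    w <- nchar(gen[1]) / 2
    g1 <- as.integer(substr(gen, 1, w))
    g2 <- as.integer(substr(gen, w + 1, 2 * w))
    g1[g1 == 0L] <- NA_integer_; g2[g2 == 0L] <- NA_integer_
    a1[i, ] <- g1; a2[i, ] <- g2
  }
  rownames(a1) <- rownames(a2) <- ids
  genotypeTable(a1, a2)
}

#' Write genotypes as a wide CSV (two columns per locus)
#'
#' @param genotypes a [genotypeTable].
#' @param path output file.
#' @export
writeGenotypesCsv <- function(genotypes, path) {
  a1 <- genotypes$a1; a2 <- genotypes$a2
  out <- data.frame(id = rownames(a1), stringsAsFactors = FALSE)
  for (l in colnames(a1)) {
    out[[paste0(l, "_1")]] <- a1[, l]
    out[[paste0(l, "_2")]] <- a2[, l]
  }
  utils::write.csv(out, path, row.names = FALSE)
}

#' Read genotypes from a wide CSV (two columns per locus)
#'
#' @param path CSV with an `id` column and `<locus>_1`/`<locus>_2` pairs.
#' @return a [genotypeTable].
#' @export
readGenotypesCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  loci <- unique(sub("_[12]$", "", setdiff(names(d), "id")))
  a1 <- as.matrix(d[paste0(loci, "_1")]); a2 <- as.matrix(d[paste0(loci, "_2")])
  dimnames(a1) <- dimnames(a2) <- list(d$id, loci)
  genotypeTable(a1, a2)
}

#' Write the five linked tables of a colony to a directory
#'
#' Emits `events.csv`, `births.csv` (with ISO dates), `pedigree.csv`,
#' `layout.csv`, `genotypes.csv`, `genotypes.gen` (GenePop),
#' `detections.csv` and, for simulated colonies, `truth.json`.
#'
#' @param colony a [ColonyDataset].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeColony <- function(colony, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) {
    utils::write.csv(d, file.path(dir, f), row.names = FALSE)
    file.path(dir, f)
  }
  births <- colonyBirths(colony)
  births$date <- as.character(dayToDate(births$day))
  ped <- colonyPedigree(colony)
  ped$date <- as.character(dayToDate(ped$day))
  paths <- c(w(colonyEvents(colony), "events.csv"),
             w(births, "births.csv"),
             w(ped, "pedigree.csv"),
             w(colonyLayout(colony), "layout.csv"),
             w(colonyDetections(colony), "detections.csv"))
  writeGenotypesCsv(colonyGenotypes(colony), file.path(dir, "genotypes.csv"))
  writeGenePop(colonyGenotypes(colony), file.path(dir, "genotypes.gen"))
  paths <- c(paths, file.path(dir, c("genotypes.csv", "genotypes.gen")))
  tr <- simTruth(colony)
  if (length(tr)) {
    keep <- tr[c("decisions", "options", "mode", "powerA", "checkDays")]
    jsonlite::write_json(keep[!vapply(keep, is.null, logical(1))],
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    paths <- c(paths, file.path(dir, "truth.json"))
  }
  invisible(paths)
}

#' Load a colony written by [writeColony()]
#'
#' @param dir directory holding the CSV files.
#' @return a [ColonyDataset] (without simulation ground truth).
#' @export
loadColony <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  births <- rd("births.csv"); births$date <- NULL
  ped <- rd("pedigree.csv"); ped$date <- NULL
  det <- if (file.exists(file.path(dir, "detections.csv")))
    rd("detections.csv") else NULL
  ColonyDataset(events = rd("events.csv"), births = births, pedigree = ped,
                genotypes = readGenotypesCsv(file.path(dir, "genotypes.csv")),
                layout = rd("layout.csv"), detections = det)
}
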