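#' Multilocus codominant genotype table
#'
#' Compact container for unordered allele pairs at codominant (microsatellite)
#' loci. Alleles are coded as positive integers per locus; `NA` marks a missing
#' genotype. Pairs are stored canonically with `allele1 <= allele2`.
#'
#' @param allele1,allele2 integer matrices (individuals x loci) holding the two
#'   alleles of each genotype; dimnames give individual ids and locus names.
#' @param founderFreqs optional list of the generating allele frequencies per
#'   locus (simulation ground truth).
#' @return An object of class `genotypeTable`.
#' @export
genotypeTable <- function(allele1, allele2, founderFreqs = NULL) {
  stopifnot(is.matrix(allele1), is.matrix(allele2),
            all(dim(allele1) == dim(allele2)))
  if (is.null(rownames(allele1))) stop("individual ids (rownames) required")
  if (is.null(colnames(allele1)))
    colnames(allele1) <- colnames(allele2) <- paste0("L", seq_len(ncol(allele1)))
  swap <- !is.na(allele1) & !is.na(allele2) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]; allele1[swap] <- allele2[swap]; allele2[swap] <- tmp
  }
  bad <- xor(is.na(allele1), is.na(allele2))
  if (any(bad)) { allele1[bad] <- NA; allele2[bad] <- NA }
  structure(list(a1 = allele1, a2 = allele2, founderFreqs = founderFreqs),
            class = "genotypeTable")
}

#' @export
print.genotypeTable <- function(x, ...) {
  cat(sprintf("genotypeTable: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$a1), ncol(x$a1), 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.genotypeTable <- function(x) dim(x$a1)

# Subset a genotype table by individual ids (character) or indices.
#' @export
`[.genotypeTable` <- function(x, i, ...) {
  genotypeTable(x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                founderFreqs = x$founderFreqs)
}

#' Ids of the individuals in a genotype table
#' @param x a `genotypeTable`.
#' @return character vector of individual ids.
#' @export
genotypeIds <- function(x) rownames(x$a1)

#' Names of the loci in a genotype table
#' @param x a `genotypeTable`.
#' @return character vector of locus names.
#' @export
lociNames <- function(x) colnames(x$a1)

setOldClass("genotypeTable")

#' ColonyDataset: the five linked tables of a barn colony study
#'
#' S4 container holding the raw material of the analysis: the antenna event
#' log, the birth/litter table, the pedigree, the multilocus genotypes, and the
#' nest-box layout, plus (optionally) per-nest-check detections and simulation
#' ground truth. All downstream functions consume this object or its parts.
#'
#' Slots:
#' \describe{
#'   \item{events}{data.frame(tag, box, entry_s, exit_s): one row per nest-box
#'     stay; times in seconds from the epoch; per tag, stays never overlap.}
#'   \item{births}{data.frame(mother, day, box, litterSize, observedSize,
#'     discoveryAge): one row per litter.}
#'   \item{pedigree}{data.frame(id, dam, sire, day, sex): dam/sire `NA` for
#'     founders; parents born before offspring.}
#'   \item{genotypes}{a [genotypeTable].}
#'   \item{layout}{data.frame(box, x, y, section): nest-box coordinates in cm.}
#'   \item{detections}{data.frame(id, check, day, box): nest-check detections
#'     used for the spatial analysis (may have 0 rows).}
#'   \item{truth}{list of simulation ground truth (empty for field data).}
#'   \item{config}{list; the simulation configuration, if simulated.}
#' }
#'
#' @name ColonyDataset-class
#' @aliases ColonyDataset
#' @exportClass ColonyDataset
setClass("ColonyDataset",
  representation(events = "data.frame", births = "data.frame",
                 pedigree = "data.frame", genotypes = "genotypeTable",
                 layout = "data.frame", detections = "data.frame",
                 truth = "list", config = "list"))

setValidity("ColonyDataset", function(object) {
  msg <- character()
  ev <- object@events
  need <- c("tag", "box", "entry_s", "exit_s")
  if (!all(need %in% names(ev))) {
    msg <- c(msg, sprintf("events must have columns %s", paste(need, collapse = ", ")))
  } else if (nrow(ev)) {
    if (any(ev$exit_s <= ev$entry_s)) msg <- c(msg, "events: exit_s must exceed entry_s")
    dt <- data.table::as.data.table(ev)[order(tag, entry_s)]
    ok <- dt[, all(entry_s[-1] >= exit_s[-.N]) || .N == 1L, by = tag]$V1
    if (!all(ok)) msg <- c(msg, "events: per-tag stays must not overlap")
  }
  bt <- object@births
  if (nrow(bt)) {
    if (any(bt$observedSize > bt$litterSize))
      msg <- c(msg, "births: observedSize cannot exceed litterSize")
    if (any(bt$discoveryAge < 1)) msg <- c(msg, "births: discoveryAge must be >= 1")
  }
  pd <- object@pedigree
  if (nrow(pd)) {
    i <- match(pd$dam, pd$id); j <- match(pd$sire, pd$id)
    if (any(pd$day[!is.na(i)] <= pd$day[i[!is.na(i)]], na.rm = TRUE) ||
        any(pd$day[!is.na(j)] <= pd$day[j[!is.na(j)]], na.rm = TRUE))
      msg <- c(msg, "pedigree: parents must be born before their offspring")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ColonyDataset
#'
#' @param events,births,pedigree,layout data.frames as documented in
#'   [ColonyDataset-class].
#' @param genotypes a [genotypeTable].
#' @param detections optional data.frame of nest-check detections.
#' @param truth,config optional lists of simulation ground truth/configuration.
#' @return a validated `ColonyDataset`.
#' @export
ColonyDataset <- function(events, births, pedigree, genotypes, layout,
                          detections = NULL, truth = list(), config = list()) {
  if (is.null(detections))
    detections <- data.frame(id = character(), check = integer(),
                             day = integer(), box = integer())
  new("ColonyDataset", events = as.data.frame(events),
      births = as.data.frame(births), pedigree = as.data.frame(pedigree),
      genotypes = genotypes, layout = as.data.frame(layout),
      detections = as.data.frame(detections), truth = truth, config = config)
}

#' @describeIn ColonyDataset-class antenna event log accessor
#' @param x a `ColonyDataset`.
#' @export
colonyEvents <- function(x) x@events

#' @describeIn ColonyDataset-class birth table accessor
#' @export
colonyBirths <- function(x) x@births

#' @describeIn ColonyDataset-class pedigree accessor
#' @export
colonyPedigree <- function(x) x@pedigree

#' @describeIn ColonyDataset-class genotype table accessor
#' @export
colonyGenotypes <- function(x) x@genotypes

#' @describeIn ColonyDataset-class nest-box layout accessor
#' @export
colonyLayout <- function(x) x@layout

#' @describeIn ColonyDataset-class nest-check detections accessor
#' @export
colonyDetections <- function(x) x@detections

#' @describeIn ColonyDataset-class simulation ground-truth accessor
#' @export
simTruth <- function(x) x@truth

setMethod("show", "ColonyDataset", function(object) {
  cat("ColonyDataset\n")
  cat(sprintf("  events:     %d stays, %d tagged individuals\n",
              nrow(object@events), length(unique(object@events$tag))))
  cat(sprintf("  births:     %d litters by %d mothers\n",
              nrow(object@births), length(unique(object@births$mother))))
  cat(sprintf("  pedigree:   %d individuals (%d founders)\n",
              nrow(object@pedigree),
              sum(is.na(object@pedigree$dam) & is.na(object@pedigree$sire))))
  cat(sprintf("  genotypes:  %d x %d loci\n", nrow(object@genotypes$a1),
              ncol(object@genotypes$a1)))
  cat(sprintf("  layout:     %d nest boxes\n", nrow(object@layout)))
  if (nrow(object@detections))
    cat(sprintf("  detections: %d records over %d nest checks\n",
                nrow(object@detections), length(unique(object@detections$check))))
  if (length(object@truth)) cat("  simulation ground truth attached\n")
  invisible(NULL)
})
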