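#' Construct a perturbation design
#'
#' @param sampleIds character sample identifiers.
#' @param ligandMatrix,drugMatrix samples x perturbations binary matrices
#'   (named columns); `NULL` for none.
#' @param drugTargets named list drug -> target node ids.
#' @param ligandReceptors named list ligand -> receptor node ids.
#' @return a [PerturbationDesign-class].
#' @export
perturbationDesign <- function(sampleIds, ligandMatrix = NULL,
                               drugMatrix = NULL, drugTargets = list(),
                               ligandReceptors = list()) {
  B <- length(sampleIds)
  if (is.null(ligandMatrix))
    ligandMatrix <- matrix(0, B, 0, dimnames = list(sampleIds, NULL))
  if (is.null(drugMatrix))
    drugMatrix <- matrix(0, B, 0, dimnames = list(sampleIds, NULL))
  methods::new("PerturbationDesign", sampleIds = as.character(sampleIds),
               ligandMatrix = ligandMatrix, drugMatrix = drugMatrix,
               drugTargets = drugTargets, ligandReceptors = ligandReceptors)
}

#' @describeIn perturbationDesign subset samples of a design
#' @param x a [PerturbationDesign-class].
#' @param i sample indices (numeric, logical or ids).
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "PerturbationDesign", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleIds)
  methods::new("PerturbationDesign", sampleIds = x@sampleIds[i],
               ligandMatrix = x@ligandMatrix[i, , drop = FALSE],
               drugMatrix = x@drugMatrix[i, , drop = FALSE],
               drugTargets = x@drugTargets,
               ligandReceptors = x@ligandReceptors)
})

#' Construct a phosphosite-to-node assignment
#'
#' @param siteIds character phosphosite identifiers (GENE:RESIDUEposition).
#' @param siteNodes character node id carrying each site.
#' @return a [SiteAssignment-class].
#' @export
siteAssignment <- function(siteIds, siteNodes) {
  methods::new("SiteAssignment", siteIds = as.character(siteIds),
               siteNodes = as.character(siteNodes))
}

#' Construct a phosphoproteomic time course
#'
#' @param values sites x times x samples numeric array.
#' @param siteIds,times,sampleIds dimension annotations.
#' @param mask logical array of observations (default all observed).
#' @return a [PhosphoTimeCourse-class].
#' @export
phosphoTimeCourse <- function(values, siteIds, times, sampleIds,
                              mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  methods::new("PhosphoTimeCourse", values = values, mask = mask,
               siteIds = as.character(siteIds), times = as.numeric(times),
               sampleIds = as.character(sampleIds))
}

#' Subset a time course to a set of timepoints
#'
#' @param tc a [PhosphoTimeCourse-class].
#' @param times times (minutes) to keep; must all be present.
#' @return the restricted [PhosphoTimeCourse-class].
#' @export
subsetTimes <- function(tc, times) {
  idx <- match(times, tc@times)
  if (anyNA(idx)) stop("requested times not present in the time course")
  phosphoTimeCourse(tc@values[, idx, , drop = FALSE], tc@siteIds,
                    tc@times[idx], tc@sampleIds,
                    tc@mask[, idx, , drop = FALSE])
}

#' Read/write the long-format phosphosite intensity table
#'
#' The canonical on-disk dialect is long format with columns `sample`,
#' `time_min`, `site_id`, `value`, `replicate`; wide format (one `site_id`
#' column plus one column per `sample@time` combination) is accepted on read
#' and pivoted. Replicate measurements of the same (sample, time, site) cell
#' are averaged into the tensor; unmeasured cells become masked missing
#' values. All times are minutes as floats.
#'
#' @param path TSV file.
#' @param format `"long"` (default) or `"wide"`.
#' @return a [PhosphoTimeCourse-class].
#' @export
readPhosphoTable <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "wide") {
    if (!"site_id" %in% names(tab)) stop("wide table needs a site_id column")
    cols <- setdiff(names(tab), "site_id")
    parts <- strsplit(cols, "@", fixed = TRUE)
    long <- do.call(rbind, lapply(seq_along(cols), function(j)
      data.frame(sample = parts[[j]][1],
                 time_min = as.numeric(parts[[j]][2]),
                 site_id = tab$site_id, value = tab[[cols[j]]],
                 replicate = 1L)))
    tab <- long
  }
  need <- c("sample", "time_min", "site_id", "value")
  if (!all(need %in% names(tab)))
    stop("missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  sites <- sort(unique(tab$site_id))
  times <- sort(unique(as.numeric(tab$time_min)))
  samples <- unique(tab$sample)
  vals <- array(NA_real_, c(length(sites), length(times), length(samples)))
  idx <- cbind(match(tab$site_id, sites),
               match(as.numeric(tab$time_min), times),
               match(tab$sample, samples))
  agg <- tapply(tab$value, interaction(idx[, 1], idx[, 2], idx[, 3],
                                       drop = TRUE), mean)
  coords <- do.call(rbind, lapply(strsplit(names(agg), ".", fixed = TRUE),
                                  as.integer))
  vals[coords] <- agg
  phosphoTimeCourse(vals, sites, times, samples, mask = !is.na(vals))
}

#' @rdname readPhosphoTable
#' @param tc a [PhosphoTimeCourse-class].
#' @export
writePhosphoTable <- function(tc, path) {
  d <- dim(tc@values)
  grid <- expand.grid(site = seq_len(d[1]), time = seq_len(d[2]),
                      sample = seq_len(d[3]))
  keep <- tc@mask[as.matrix(grid)]
  long <- data.frame(sample = tc@sampleIds[grid$sample],
                     time_min = tc@times[grid$time],
                     site_id = tc@siteIds[grid$site],
                     # 17 significant digits: doubles round-trip bit-exactly
                     value = sprintf("%.17g", tc@values[as.matrix(grid)]),
                     replicate = 1L)[keep, ]
  long <- long[order(long$sample, long$time_min, long$site_id), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a site-to-node assignment TSV (`site_id`, `node_id`)
#'
#' @param path TSV file.
#' @return a [SiteAssignment-class].
#' @export
readSiteAssignment <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "node_id") %in% names(tab)))
    stop("assignment table needs site_id and node_id columns")
  siteAssignment(tab$site_id, tab$node_id)
}

#' @rdname readSiteAssignment
#' @param assignment a [SiteAssignment-class].
#' @export
writeSiteAssignment <- function(assignment, path) {
  utils::write.table(data.frame(site_id = assignment@siteIds,
                                node_id = assignment@siteNodes),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a two-column perturbation-to-target map (`drug`, `target`)
#'
#' Multiple rows per drug give multi-target drugs.
#'
#' @param path TSV file.
#' @return named list drug -> character vector of targets.
#' @export
readDrugTargets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("drug", "target") %in% names(tab)))
    stop("drug-target table needs drug and target columns")
  split(tab$target, tab$drug)
}

#' @rdname readDrugTargets
#' @param targets named list drug -> targets.
#' @export
writeDrugTargets <- function(targets, path) {
  tab <- data.frame(drug = rep(names(targets), lengths(targets)),
                    target = unlist(targets, use.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a perturbation design TSV
#'
#' Columns `sample`, `ligand`, `drug`; the perturbation columns hold
#' comma-separated lists (empty for none).
#'
#' @param path TSV file.
#' @param drugTargets,ligandReceptors named lists mapping perturbations to
#'   network nodes (see [readDrugTargets()]).
#' @return a [PerturbationDesign-class].
#' @export
readDesign <- function(path, drugTargets = list(), ligandReceptors = list()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("sample", "ligand", "drug") %in% names(tab)))
    stop("design table needs sample, ligand and drug columns")
  splitList <- function(x) lapply(strsplit(x, ","), function(v)
    v[nzchar(trimws(v))])
  ligs <- splitList(tab$ligand)
  drugs <- splitList(tab$drug)
  allLig <- sort(unique(unlist(ligs)))
  allDrug <- sort(unique(unlist(drugs)))
  B <- nrow(tab)
  LM <- matrix(0, B, length(allLig), dimnames = list(tab$sample, allLig))
  DM <- matrix(0, B, length(allDrug), dimnames = list(tab$sample, allDrug))
  for (i in seq_len(B)) {
    LM[i, unlist(ligs[i])] <- 1
    DM[i, unlist(drugs[i])] <- 1
  }
  perturbationDesign(tab$sample, LM, DM, drugTargets, ligandReceptors)
}

#' @rdname readDesign
#' @param design a [PerturbationDesign-class].
#' @export
writeDesign <- function(design, path) {
  collapse <- function(M) apply(M, 1, function(r)
    paste(colnames(M)[r != 0], collapse = ","))
  tab <- data.frame(sample = design@sampleIds,
                    ligand = if (ncol(design@ligandMatrix))
                      collapse(design@ligandMatrix) else "",
                    drug = if (ncol(design@drugMatrix))
                      collapse(design@drugMatrix) else "")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
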