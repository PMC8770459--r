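#' @include rnl.R synthetic-data.R
NULL

.GROUPS <- c("flower_vs_leaf", "beetle_vs_leaf", "beetle_vs_flower")

#' ComparisonSummary: contrasts aggregated over systems and groups
#'
#' Holds the full pairwise contrast table for every (visual system,
#' comparison group) combination, per-system mean contrasts, and per-sample
#' means (each A-item averaged over all B-items, the quantity typically
#' plotted).
#'
#' @slot contrasts `data.frame` with columns `system`, `group`, `labelA`,
#'   `labelB`, `deltaS`.
#' @slot means `data.frame` with columns `system`, `group`, `meanDeltaS`,
#'   `nPairs`.
#' @slot perSample `data.frame` with columns `system`, `group`, `labelA`,
#'   `meanDeltaS`.
#' @slot systems system labels in presentation order.
#' @export
setClass("ComparisonSummary",
  representation(contrasts = "data.frame", means = "data.frame",
                 perSample = "data.frame", systems = "character"))

setMethod("show", "ComparisonSummary", function(object) {
  cat("ComparisonSummary:", nrow(object@contrasts), "pairwise contrasts,",
      length(object@systems), "visual systems\n")
  wide <- stats::reshape(object@means[, c("system", "group", "meanDeltaS")],
                         idvar = "system", timevar = "group",
                         direction = "wide")
  names(wide) <- sub("meanDeltaS\\.", "", names(wide))
  rownames(wide) <- NULL
  print(wide, digits = 4)
})

#' Mean contrasts of a comparison summary
#'
#' @param x a [ComparisonSummary-class].
#' @return `data.frame` of per-(system, group) mean contrasts.
#' @export
meanContrasts <- function(x) {
  stopifnot(is(x, "ComparisonSummary"))
  x@means
}

#' All pairwise contrasts of a comparison summary
#'
#' @param x a [ComparisonSummary-class].
#' @param system,group optional filters.
#' @return `data.frame` of pairwise contrasts.
#' @export
contrastTable <- function(x, system = NULL, group = NULL) {
  stopifnot(is(x, "ComparisonSummary"))
  tab <- x@contrasts
  if (!is.null(system)) tab <- tab[tab$system %in% system, ]
  if (!is.null(group)) tab <- tab[tab$group %in% group, ]
  tab
}

#' Per-sample mean contrasts of a comparison summary
#'
#' Each group-A sample's contrast averaged over all group-B samples.
#'
#' @param x a [ComparisonSummary-class].
#' @return `data.frame` of per-sample means.
#' @export
perSampleMeans <- function(x) {
  stopifnot(is(x, "ComparisonSummary"))
  x@perSample
}

#' Pairwise contrasts between two spectrum collections
#'
#' Receptor-noise-limited contrast of every A x B spectrum pair under one
#' visual system, illuminant and adapting background. Computation is
#' vectorized over pairs via per-class catch matrices; results equal
#' [chromaticContrast()] pair by pair.
#'
#' @param groupA,groupB nonempty named lists of reflectance
#'   [Spectrum-class] objects.
#' @param system a [VisualSystem-class].
#' @param illum an [Illuminant-class] (absolute photon flux in quantum
#'   mode).
#' @param background adapting reflectance [Spectrum-class], by convention
#'   the mean leaf of the run.
#' @param kappa,floorRatio as in [chromaticContrast()].
#' @return `data.frame` with one row per pair: `labelA`, `labelB`, one
#'   `df_<class>` column of log-signal differences per receptor class, and
#'   `deltaS`.
#' @export
pairwiseContrasts <- function(groupA, groupB, system, illum, background,
                              kappa = 1e-14, floorRatio = 1e-12) {
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("comparison groups must be nonempty")
  quantum <- noiseMode(system) == "quantum"
  if (quantum && (illum@scale != "absolute" ||
                  specKind(illum) != "irradiance-photon"))
    stop("quantum noise mode requires an absolute photon-flux illuminant")
  Qbg <- catchMatrix(system, list(background), illum)[, 1L]
  if (any(Qbg <= 0))
    stop("degenerate background: background catch must be positive in ",
         "every receptor class")
  QA <- floorCatches(catchMatrix(system, groupA, illum), floorRatio, "A")
  QB <- floorCatches(catchMatrix(system, groupB, illum), floorRatio, "B")
  lnA <- log(QA / Qbg)
  lnB <- log(QB / Qbg)
  n <- nrow(QA)
  nA <- ncol(QA); nB <- ncol(QB)
  Df <- lapply(seq_len(n), function(i) outer(lnA[i, ], lnB[i, ], "-"))
  if (quantum) {
    eta <- densities(system)
    E2 <- lapply(seq_len(n), function(i)
      system@nu^2 / eta[i] + 2 / outer(kappa * QA[i, ], kappa * QB[i, ],
                                       "+"))
  } else {
    e <- receptorNoise(system)
    E2 <- lapply(seq_len(n), function(i)
      matrix(e[i]^2, nA, nB))
  }
  num <- matrix(0, nA, nB)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    w <- matrix(1, nA, nB)
    for (k in setdiff(seq_len(n), c(i, j))) w <- w * E2[[k]]
    num <- num + w * (Df[[i]] - Df[[j]])^2
  }
  den <- matrix(0, nA, nB)
  for (i in seq_len(n)) {
    w <- matrix(1, nA, nB)
    for (k in setdiff(seq_len(n), i)) w <- w * E2[[k]]
    den <- den + w
  }
  ds <- sqrt(num / den)
  out <- data.frame(labelA = rep(colnames(QA), times = nB),
                    labelB = rep(colnames(QB), each = nA),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n))
    out[[paste0("df_", rownames(QA)[i])]] <- as.vector(Df[[i]])
  out$deltaS <- as.vector(ds)
  out
}

# Standard comparison groups of a synthetic (or loaded) dataset.
dataset_groups <- function(dataset) {
  list(flower_vs_leaf = list(A = dataset$flowers, B = dataset$leaves),
       beetle_vs_leaf = list(A = dataset$beetles, B = dataset$leaves),
       beetle_vs_flower = list(A = dataset$beetles, B = dataset$flowers))
}

#' Compare visual systems across the standard comparison groups
#'
#' Computes all pairwise contrasts for the three comparison groups (flower
#' vs leaf, beetle vs leaf, beetle vs flower) under each visual system, with
#' a single mean-leaf adapting background shared by all groups.
#'
#' @param dataset list with elements `beetles`, `flowers`, `leaves` (named
#'   lists of reflectance [Spectrum-class]), e.g. from [genDataset()] or
#'   assembled from [readSpectraTable()].
#' @param systems list of [VisualSystem-class] objects (or a character
#'   vector of names for [buildNamedSystem()]).
#' @param illum an [Illuminant-class].
#' @param background adapting background; default the pointwise mean of
#'   `dataset$leaves`.
#' @param kappa photon-catch scaling for quantum mode.
#' @return A [ComparisonSummary-class].
#' @examples
#' ds <- genDataset(DatasetSpec(nBeetles = 3, nFlowers = 3, nLeaves = 3))
#' compareSystems(ds, c("USM", "USML"), d65())
#' @export
compareSystems <- function(dataset, systems, illum,
                           background = NULL, kappa = 1e-14) {
  if (is.character(systems)) {
    labs <- systems
    systems <- lapply(systems, buildNamedSystem,
                      grid = wavelengths(dataset$leaves[[1L]]))
    names(systems) <- labs
  }
  labs <- vapply(systems, specLabel, character(1))
  if (is.null(background)) background <- meanSpectrum(dataset$leaves)
  groups <- dataset_groups(dataset)
  contrasts <- list()
  for (s in seq_along(systems)) for (g in names(groups)) {
    tab <- pairwiseContrasts(groups[[g]]$A, groups[[g]]$B, systems[[s]],
                             illum, background, kappa = kappa)
    contrasts[[length(contrasts) + 1L]] <-
      data.frame(system = unname(labs[s]), group = g,
                 tab[, c("labelA", "labelB", "deltaS")],
                 stringsAsFactors = FALSE)
  }
  contrasts <- do.call(rbind, contrasts)
  means <- stats::aggregate(deltaS ~ system + group, contrasts, mean)
  names(means)[names(means) == "deltaS"] <- "meanDeltaS"
  counts <- stats::aggregate(deltaS ~ system + group, contrasts, length)
  means$nPairs <- counts$deltaS[match(paste(means$system, means$group),
                                      paste(counts$system, counts$group))]
  perSample <- stats::aggregate(deltaS ~ system + group + labelA,
                                contrasts, mean)
  names(perSample)[names(perSample) == "deltaS"] <- "meanDeltaS"
  new("ComparisonSummary", contrasts = contrasts, means = means,
      perSample = perSample, systems = labs)
}

#' Percent difference in mean contrast between two systems
#'
#' pct(X, Y) = 100 * (mean_X - mean_Y) / mean_Y for one comparison group.
#'
#' @param summary a [ComparisonSummary-class].
#' @param systemX,systemY system labels.
#' @param group comparison group name.
#' @return Percent difference (numeric scalar).
#' @export
percentDifference <- function(summary, systemX, systemY, group) {
  m <- meanContrasts(summary)
  pick <- function(s) {
    v <- m$meanDeltaS[m$system == s & m$group == group]
    if (length(v) != 1L) stop("no unique mean for ", s, " / ", group)
    v
  }
  100 * (pick(systemX) - pick(systemY)) / pick(systemY)
}

# Tetrachromat with the LWS peak moved to `target`, built by `mech`.
build_sweep_system <- function(target, mech, grid, ...) {
  lm <- c(UVS = 355, SWS = 445, MWS = 530, LWS = target)
  dens <- densityPreset("beetle")
  recs <- lapply(lm, function(l) {
    if (l > 570) {
      if (mech == "filter") filterShiftedReceptor(l, grid = grid, ...)
      else opsinShiftedReceptor(l, grid = grid)
    } else a1Template(l, grid = grid)
  })
  VisualSystem(recs, dens, nu = deriveNu(0.12, dens[["LWS"]]),
               label = sprintf("VS%g", target))
}

#' Sweep the long-wavelength receptor peak
#'
#' Builds tetrachromats whose LWS peak walks through `targets` (by the
#' requested red-shift mechanism) and summarizes contrasts for each.
#'
#' @param dataset as in [compareSystems()].
#' @param targets ascending LWS peak wavelengths in nm.
#' @param mech `"filter"` or `"opsin"`.
#' @param illum an [Illuminant-class].
#' @param background,kappa as in [compareSystems()].
#' @return A [ComparisonSummary-class] with systems `VS<target>` in sweep
#'   order.
#' @seealso [stepwiseIncreases()] for the consecutive percent changes.
#' @export
sweepLws <- function(dataset, targets = c(580, 600, 620, 640, 660),
                     mech = c("filter", "opsin"), illum,
                     background = NULL, kappa = 1e-14) {
  mech <- match.arg(mech)
  stopifnot(all(diff(targets) > 0) || length(targets) == 1L)
  grid <- wavelengths(dataset$leaves[[1L]])
  systems <- lapply(targets, build_sweep_system, mech = mech, grid = grid)
  compareSystems(dataset, systems, illum, background = background,
                 kappa = kappa)
}

#' Stepwise percent increases along a system sweep
#'
#' Percent change of the mean contrast between consecutive systems of a
#' summary (in its stored system order), for one comparison group.
#'
#' @param summary a [ComparisonSummary-class].
#' @param group comparison group name.
#' @return Named numeric vector of consecutive percent changes.
#' @export
stepwiseIncreases <- function(summary, group) {
  sys <- summary@systems
  if (length(sys) < 2L) return(numeric(0))
  out <- vapply(seq_len(length(sys) - 1L), function(i)
    percentDifference(summary, sys[i + 1L], sys[i], group), numeric(1))
  names(out) <- paste(sys[-1L], sys[-length(sys)], sep = " vs ")
  out
}

#' Paired sign-flip permutation test between two contrast tables
#'
#' Descriptive significance check for the difference in mean contrast
#' between two visual systems evaluated on identical spectrum pairs: the
#' per-pair contrast differences have their signs flipped at random and the
#' two-sided p-value is (1 + #{|permuted mean| >= |observed mean|}) /
#' (nPerm + 1).
#'
#' @param tableX,tableY `data.frame`s with columns `labelA`, `labelB`,
#'   `deltaS` over the same pair set (e.g. from [contrastTable()]).
#' @param nPerm number of permutations.
#' @param seed optional RNG seed.
#' @return p-value in (0, 1].
#' @export
permutationTest <- function(tableX, tableY, nPerm = 999, seed = NULL) {
  keyX <- paste(tableX$labelA, tableX$labelB)
  keyY <- paste(tableY$labelA, tableY$labelB)
  if (!setequal(keyX, keyY) || anyDuplicated(keyX))
    stop("the two tables must cover the same set of spectrum pairs")
  d <- tableX$deltaS - tableY$deltaS[match(keyX, keyY)]
  obs <- mean(d)
  perm <- with_seed_or_not(seed, {
    signs <- matrix(sample(c(-1, 1), length(d) * nPerm, replace = TRUE),
                    nrow = length(d))
    colMeans(d * signs)
  })
  (1 + sum(abs(perm) >= abs(obs))) / (nPerm + 1)
}
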