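#' @include phantom.R
NULL

#' Cohort recipe
#'
#' Composition of a synthetic lung-SBRT cohort. The default mix reproduces a
#' typical institutional case load: 26 patients at 48 Gy/4 fr, 3 at
#' 60 Gy/8 fr and 1 at 60 Gy/15 fr, with upper lobes and right-sided lesions
#' predominating.
#'
#' @slot nPatients total number of cases
#' @slot mix data.frame with columns `rx`, `fr`, `count` (counts sum to
#'   `nPatients`)
#' @slot stress in \[0, 1\]: how close each case's binding organ constraint
#'   sits to its limit (see [makePhantom()])
#' @slot seed integer master seed; per-case seeds are derived from it
#' @export
setClass("CohortRecipe",
  representation(nPatients = "integer", mix = "data.frame",
                 stress = "numeric", seed = "integer"))

setValidity("CohortRecipe", function(object) {
  msg <- character()
  if (!all(c("rx", "fr", "count") %in% names(object@mix)))
    msg <- c(msg, "'mix' needs rx/fr/count columns")
  else if (sum(object@mix$count) != object@nPatients)
    msg <- c(msg, "mix counts must sum to nPatients")
  if (object@stress < 0 || object@stress > 1)
    msg <- c(msg, "'stress' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param nPatients,stress,seed see slots
#' @param mix prescription mix; when `nPatients` differs from the mix total,
#'   counts are rescaled proportionally (largest-remainder rounding)
#' @rdname CohortRecipe-class
#' @export
cohortRecipe <- function(nPatients = 30L, mix = defaultPrescriptionMix(),
                         stress = 0.9, seed = 1L) {
  nPatients <- as.integer(nPatients)
  if (sum(mix$count) != nPatients) {
    exact <- mix$count / sum(mix$count) * nPatients
    cnt <- floor(exact)
    rem <- nPatients - sum(cnt)
    if (rem > 0) {
      ord <- order(exact - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    mix$count <- as.integer(cnt)
  }
  new("CohortRecipe", nPatients = nPatients, mix = mix,
      stress = stress, seed = as.integer(seed))
}

#' @rdname CohortRecipe-class
#' @export
defaultPrescriptionMix <- function() {
  data.frame(rx = c(48, 60, 60), fr = c(4L, 8L, 15L), count = c(26L, 3L, 1L))
}

setMethod("show", "CohortRecipe", function(object) {
  cat(sprintf("CohortRecipe: %d patients, stress %.2f, seed %d\n",
              object@nPatients, object@stress, object@seed))
  for (i in seq_len(nrow(object@mix)))
    cat(sprintf("  %g Gy / %d fr: %d\n", object@mix$rx[i],
                object@mix$fr[i], object@mix$count[i]))
})

# Tumour-site sequence for one prescription group, following the lobe and
# laterality proportions of a typical cohort (upper lobes and right side
# predominate). Deterministic given the group size.
.siteSequence <- function(n, lobeWeights = c(upper = 20, middle = 3, lower = 3),
                          latWeights = c(left = 10, right = 16)) {
  rep_weighted <- function(w, n) {
    exact <- w / sum(w) * n
    cnt <- floor(exact)
    rem <- n - sum(cnt)
    if (rem > 0) {
      ord <- order(exact - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    rep(names(w), times = cnt)
  }
  data.frame(lobe = rep_weighted(lobeWeights, n),
             laterality = rep_weighted(latWeights, n),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Builds `nPatients` cases with the recipe's prescription mix and a
#' lobe/laterality distribution matching the default cohort composition.
#' Per-case seeds derive deterministically from the recipe seed, so the same
#' recipe reproduces the same cohort.
#'
#' @param recipe a [CohortRecipe-class]
#' @param geometry grid for every case
#' @param verbose emit one message per case
#' @return list of [PatientCase-class]
#' @export
makeCohort <- function(recipe, geometry = defaultPhantomGeometry(),
                       verbose = FALSE) {
  validObject(recipe)
  cases <- vector("list", recipe@nPatients)
  idx <- 0L
  for (grp in seq_len(nrow(recipe@mix))) {
    n <- recipe@mix$count[grp]
    if (n == 0L) next
    rx <- recipe@mix$rx[grp]; fr <- recipe@mix$fr[grp]
    sites <- if (fr == 4L) .siteSequence(n)
             else .siteSequence(n, c(upper = 3, middle = 0, lower = 0),
                                c(left = 1, right = 2))
    # pair lobes and sides through a seeded shuffle
    perm <- .withSeed(recipe@seed + grp, function()
      sample.int(n, n))
    sites$laterality <- sites$laterality[perm]
    for (i in seq_len(n)) {
      idx <- idx + 1L
      caseSeed <- as.integer((recipe@seed + 7919 * idx) %% .Machine$integer.max)
      if (verbose)
        message(sprintf("generating case %d/%d (%g Gy/%d fr, %s %s, seed %d)",
                        idx, recipe@nPatients, rx, fr,
                        sites$lobe[i], sites$laterality[i], caseSeed))
      cases[[idx]] <- makePhantom(
        Prescription(rx, fr), lobe = sites$lobe[i],
        laterality = sites$laterality[i], stress = recipe@stress,
        seed = caseSeed, id = sprintf("case%02d_%gGy%dfr", idx, rx, fr),
        geometry = geometry)
    }
  }
  cases
}

#' Emit a three-case mini-cohort as fixture bundles
#'
#' Writes one case per prescription group (48 Gy/4 fr, 60 Gy/8 fr,
#' 60 Gy/15 fr) as native case bundles under `dir`, for use as a small test
#' or demonstration cohort.
#'
#' @param dir output directory (created if needed)
#' @param stress,seed forwarded to the generator
#' @return invisibly, the bundle directories
#' @export
writeFixtureCohort <- function(dir, stress = 0.9, seed = 1L) {
  recipe <- cohortRecipe(3L, data.frame(rx = c(48, 60, 60),
                                        fr = c(4L, 8L, 15L),
                                        count = c(1L, 1L, 1L)),
                         stress = stress, seed = seed)
  cases <- makeCohort(recipe)
  dirs <- vapply(cases, function(cs) {
    d <- file.path(dir, cs@id)
    writeCaseBundle(cs, d)
    d
  }, character(1))
  invisible(dirs)
}
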