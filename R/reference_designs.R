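#' Build the eight reference designs plus a shared validation set
#'
#' Emulates the study grid of reference populations at the scale of the
#' simulated herd. A single validation cow set spanning all five breed
#' groups is drawn first and is disjoint from every reference:
#'
#' * Ref1 — all remaining pure Holstein (bulls + cows): within-breed H.
#' * Ref2 — all pure Jersey: within-breed J (across-breed for H).
#' * Ref3 — Ref1 and Ref2 combined (H-dominated joint purebred).
#' * Ref4 — same animals as Ref3 but predictions for crossbreds formed as
#'   the breed-proportion weighted average of Ref1 and Ref2 GEBV, with
#'   proportions from the PCA group allocation.
#' * Ref4p — as Ref4 with continuous admixture proportions.
#' * Ref5 — Ref3 plus every crossbred cow.
#' * Ref6 — breed-balanced: all J bulls + equally many H bulls, all J
#'   cows + equally many H cows (H subsets sampled randomly).
#' * Ref7 — the same balanced bulls + only crossbred cows, matched to
#'   Ref6's total size (75:25 and 25:75 groups capped at the smaller of
#'   the two, remainder from 50:50).
#' * Ref8 — Ref6's cows, Ref7's cows and the shared bulls together.
#'
#' @param population a `population`.
#' @param scheme design scheme label; only `"table1"` is defined.
#' @param validation_sizes named counts of validation cows per breed
#'   group (names from `H`, `75H25J`, `50H50J`, `25H75J`, `J`).
#' @param seed integer seed for the random subsets.
#' @return named list of `reference_design` objects (fields `name`,
#'   `reference_ids`, `validation_ids`, `combine_rule`,
#'   `component_designs`, `breed_fraction_source`).
#' @export
build_reference_designs <- function(population, scheme = "table1",
                                    validation_sizes = c(H = 75, `75H25J` = 65,
                                                         `50H50J` = 65,
                                                         `25H75J` = 25,
                                                         J = 40),
                                    seed = 1L) {
  if (!identical(scheme, "table1"))
    stop("unknown design scheme: ", scheme)
  an <- population$animals
  set.seed(seed)
  val <- character(0)
  for (grp in names(validation_sizes)) {
    pool <- an$animal_id[an$breed_group == grp & an$sex == "F"]
    k <- validation_sizes[[grp]]
    if (length(pool) < k)
      stop("design validation, group ", grp, ": only ", length(pool),
           " cows available for ", k, " requested")
    val <- c(val, sample(pool, k))
  }
  # parent-offspring exclusion: sires of validation cows never enter a
  # reference set; paternal half sibs of validation cows remain
  val_sires <- unique(an$sire_id[an$animal_id %in% val])
  val_sires <- val_sires[!is.na(val_sires)]
  avail <- an[!an$animal_id %in% c(val, val_sires), ]
  pick <- function(group, sex = NULL) {
    m <- avail$breed_group %in% group
    if (!is.null(sex)) m <- m & avail$sex == sex
    avail$animal_id[m]
  }
  need <- function(ids, design, group) {
    if (!length(ids)) stop("design ", design, ": no animals available in ",
                           "group ", group)
    ids
  }
  ref1 <- need(pick("H"), "Ref1", "H")
  ref2 <- need(pick("J"), "Ref2", "J")
  ref3 <- c(ref1, ref2)
  cross <- pick(c("75H25J", "50H50J", "25H75J"))
  ref5 <- c(ref3, need(cross, "Ref5", "crossbred"))
  h_bulls <- pick("H", "M"); j_bulls <- need(pick("J", "M"), "Ref6", "J bulls")
  h_cows <- pick("H", "F"); j_cows <- need(pick("J", "F"), "Ref6", "J cows")
  nb <- min(length(h_bulls), length(j_bulls))
  nc <- min(length(h_cows), length(j_cows))
  bulls6 <- c(sample(h_bulls, nb), sample(j_bulls, nb))
  cows6 <- c(sample(h_cows, nc), sample(j_cows, nc))
  ref6 <- c(bulls6, cows6)
  target <- 2L * nc
  a75 <- pick("75H25J", "F"); a50 <- pick("50H50J", "F")
  a25 <- pick("25H75J", "F")
  k_out <- min(length(a75), length(a25), target %/% 3L)
  n50 <- target - 2L * k_out
  if (n50 > length(a50))
    stop("design Ref7: not enough 50H50J cows (", length(a50), " for ",
         n50, ")")
  cows7 <- c(sample(a75, k_out), sample(a50, n50), sample(a25, k_out))
  ref7 <- c(bulls6, cows7)
  ref8 <- c(bulls6, cows6, cows7)
  mk <- function(name, ids, combine = "direct", components = NULL,
                 frac_source = "truth") {
    structure(list(name = name, reference_ids = unname(ids),
                   validation_ids = unname(val), combine_rule = combine,
                   component_designs = components,
                   breed_fraction_source = frac_source),
              class = "reference_design")
  }
  list(Ref1 = mk("Ref1", ref1), Ref2 = mk("Ref2", ref2),
       Ref3 = mk("Ref3", ref3),
       Ref4 = mk("Ref4", ref3, "weighted_average", c("Ref1", "Ref2"), "pca"),
       Ref4p = mk("Ref4p", ref3, "weighted_average", c("Ref1", "Ref2"),
                  "admixture"),
       Ref5 = mk("Ref5", ref5), Ref6 = mk("Ref6", ref6),
       Ref7 = mk("Ref7", ref7), Ref8 = mk("Ref8", ref8))
}

#' @export
print.reference_design <- function(x, ...) {
  cat(sprintf("reference_design %s: %d reference, %d validation (%s)\n",
              x$name, length(x$reference_ids), length(x$validation_ids),
              x$combine_rule))
  invisible(x)
}
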