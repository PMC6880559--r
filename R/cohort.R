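#' Define a sequencing cohort
#'
#' A cohort is the set of sequenced individuals: the ingroup (several species,
#' usually sampled two individuals per species, split into a northern and a
#' southern clade), exactly one intergeneric individual (the genome in which
#' candidate insertions are ascertained), and exactly one outgroup individual
#' (used to require that candidate insertions are evolutionarily recent, i.e.
#' absent from the outgroup).
#'
#' @param individuals data.frame with columns `id`, `species`, `clade`; `clade`
#'   must be one of `"north"`, `"south"`, `"intergeneric"`, `"outgroup"`.
#' @return An object of class `alu_cohort`.
#' @seealso [papio_gelada_cohort()] for the default 14-individual preset.
#' @export
cohort_spec <- function(individuals) {
  stopifnot(is.data.frame(individuals),
            all(c("id", "species", "clade") %in% names(individuals)))
  individuals$id <- as.character(individuals$id)
  individuals$species <- as.character(individuals$species)
  ok <- individuals$clade %in% c("north", "south", "intergeneric", "outgroup")
  if (!all(ok))
    stop("unknown clade value(s): ", paste(unique(individuals$clade[!ok]), collapse = ", "))
  if (anyDuplicated(individuals$id))
    stop("individual ids must be unique")
  if (sum(individuals$clade == "outgroup") != 1L)
    stop("cohort must contain exactly one outgroup individual")
  if (sum(individuals$clade == "intergeneric") != 1L)
    stop("cohort must contain exactly one intergeneric individual")
  structure(list(individuals = individuals), class = "alu_cohort")
}

#' Default cohort preset: 6 ingroup species x 2, one gelada, one macaque
#'
#' Mirrors the study design this package emulates: two individuals from each
#' of six baboon species (three species per clade), a single gelada as the
#' intergeneric ascertainment genome, and a single rhesus macaque outgroup.
#'
#' @return An `alu_cohort` with 14 individuals.
#' @export
papio_gelada_cohort <- function() {
  north <- c("anubis", "hamadryas", "papio")
  south <- c("cynocephalus", "ursinus", "kindae")
  ing <- data.frame(
    id = paste0(rep(c(north, south), each = 2), "_", 1:2),
    species = rep(c(north, south), each = 2),
    clade = rep(c("north", "south"), each = 6),
    stringsAsFactors = FALSE
  )
  extra <- data.frame(
    id = c("gelada_1", "macaca_1"),
    species = c("gelada", "macaca"),
    clade = c("intergeneric", "outgroup"),
    stringsAsFactors = FALSE
  )
  cohort_spec(rbind(ing, extra))
}

#' @export
print.alu_cohort <- function(x, ...) {
  ind <- x$individuals
  cat("Cohort of", nrow(ind), "individuals:",
      sum(ind$clade %in% c("north", "south")), "ingroup (",
      length(unique(ind$species[ind$clade %in% c("north", "south")])),
      "species ), intergeneric:", intergeneric_id(x),
      ", outgroup:", outgroup_id(x), "\n")
  invisible(x)
}

#' Cohort accessors
#'
#' @param cohort an `alu_cohort`.
#' @return Character vector(s) of individual ids or species names.
#' @export
ingroup_ids <- function(cohort) {
  ind <- cohort$individuals
  ind$id[ind$clade %in% c("north", "south")]
}

#' @rdname ingroup_ids
#' @export
intergeneric_id <- function(cohort) {
  ind <- cohort$individuals
  ind$id[ind$clade == "intergeneric"]
}

#' @rdname ingroup_ids
#' @export
outgroup_id <- function(cohort) {
  ind <- cohort$individuals
  ind$id[ind$clade == "outgroup"]
}

#' @rdname ingroup_ids
#' @param ids individual ids to map to species.
#' @export
species_of <- function(cohort, ids) {
  ind <- cohort$individuals
  ind$species[match(ids, ind$id)]
}

#' @rdname ingroup_ids
#' @export
ingroup_species <- function(cohort) {
  unique(species_of(cohort, ingroup_ids(cohort)))
}

#' @rdname ingroup_ids
#' @export
clade_of <- function(cohort, ids) {
  ind <- cohort$individuals
  ind$clade[match(ids, ind$id)]
}

#' Classify a planted locus from its carrier genotypes
#'
#' The sharing class is a pure function of the carrier copy numbers:
#' * `intergeneric_private`: carried by the intergeneric individual only;
#' * `fixed_ingroup`: carried by the intergeneric individual and all ingroup
#'   individuals;
#' * `intergeneric_shared`: carried by the intergeneric individual and a proper
#'   non-empty subset of the ingroup;
#' * `species_indicative`: not in the intergeneric individual, carried by both
#'   individuals of exactly one ingroup species and no other ingroup individual;
#' * `polymorphic_ingroup`: any other ingroup-only pattern.
#'
#' The outgroup never carries an insertion (ascertainment requires absence from
#' the outgroup); a non-zero outgroup genotype is an error.
#'
#' @param carriers named integer vector of copy numbers (0/1/2), one entry per
#'   cohort individual.
#' @param cohort an `alu_cohort`.
#' @return A single string, the sharing class.
#' @export
classify_sharing_class <- function(carriers, cohort) {
  og <- outgroup_id(cohort)
  ig <- intergeneric_id(cohort)
  ing <- ingroup_ids(cohort)
  stopifnot(all(c(og, ig, ing) %in% names(carriers)))
  if (carriers[[og]] > 0) stop("outgroup must not carry any planted insertion")
  ing_carrier <- ing[carriers[ing] > 0]
  k <- length(ing_carrier)
  if (carriers[[ig]] > 0) {
    if (k == 0L) return("intergeneric_private")
    if (k == length(ing)) return("fixed_ingroup")
    return("intergeneric_shared")
  }
  sp <- unique(species_of(cohort, ing_carrier))
  if (length(sp) == 1L &&
      setequal(ing_carrier, ing[species_of(cohort, ing) == sp]))
    return("species_indicative")
  "polymorphic_ingroup"
}
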