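#' Build the bundled feeding-muscle fixture ontology
#'
#' Programmatically constructs the subset of the Mammalian Feeding Muscle
#' Ontology used throughout the package's tests and examples: the muscles
#' attached to the mandible (with their `part_of` hierarchy), the muscles
#' innervated by the trigeminal nerve, the defined grouping class
#' 'trigeminal muscle', the worked logical definitions of the styloglossus
#' and hyoglossus, the innervation-implies-arch-origin rules (trigeminal
#' nerve to branchial arch 1, facial nerve to branchial arch 2), the
#' geniohyoid / anterior digastric disambiguation pair, and a detached
#' epiphysis/digit/hand demonstration sub-ontology for `part_of`-mediated
#' subsumption.
#'
#' The fixture is an evidence artifact: only published facts are asserted.
#' Widely known anatomy that the source material does not state (e.g. the
#' genioglossus innervation) is deliberately omitted, so absence of an
#' entailment is meaningful.  The five published class ids (styloglossus
#' MFMO:0000066, hyoglossus MFMO:0000064, hypoglossal nerve MFMO:0000301,
#' stylohyal bone MFMO:0000053, tongue MFMO:0000107) are used verbatim;
#' all other classes get sequential ids from MFMO:0000500 in declaration
#' order, so the build is deterministic (byte-identical serialization
#' across runs).  Properties use their standard ids: `part of`
#' BFO:0000050 (transitive), `attached to` RO:0002371, `innervated by`
#' RO:0002005, `develops from` RO:0002202.
#'
#' @return a validated [ontology()].
#' @examples
#' ont <- build_fixture()
#' ont
#' resolve_label(ont, "external pterygoid muscle")
#' @export
build_fixture <- function() {
  fixture_build_internal()$ontology
}

#' Fixture manifest: one row per class/axiom with its evidence tag
#'
#' The manifest is the audit table for the fixture: every class record and
#' every axiom carries a non-empty evidence tag naming the published list
#' or worked example it encodes ("mandible-attachment list", "arch-1
#' derivative list", "trigeminal-mandible list", "worked muscle
#' definition", ...).  Classes appearing in several published lists carry
#' one record per list, so tag counts match the published list lengths.
#'
#' @return a list with data.frames `class_records` (`id`, `label`, `tag`)
#'   and `axiom_records` (`axiom` key, `tag`).
#' @examples
#' m <- fixture_manifest()
#' table(m$class_records$tag)
#' @export
fixture_manifest <- function() {
  fixture_build_internal()$manifest
}

# evidence tags
T_VOCAB <- "supporting vocabulary"
T_MAND <- "mandible-attachment list"
T_ARCH1 <- "arch-1 derivative list"
T_TRIGMAND <- "trigeminal-mandible list"
T_DEF <- "worked muscle definition"
T_GCI <- "innervation-to-arch rule"
T_PAIR <- "innervation disambiguation pair"
T_ARCH2 <- "arch-2 inference example"
T_EPI <- "subsumption worked example"
T_PART <- "part hierarchy"
T_TAXON <- "taxon-specific subclass"
T_GROUP <- "innervation grouping definition"

fixture_build_internal <- function() {
  st <- new.env(parent = emptyenv())
  st$classes <- list()
  st$axioms <- list()
  st$crec <- list()   # (id, label, tag)
  st$arec <- list()   # (axiom key, tag)
  st$next_id <- 500L

  cls <- function(label, tags, synonyms = character(0), id = NULL) {
    if (is.null(id)) {
      id <- sprintf("MFMO:%07d", st$next_id)
      st$next_id <- st$next_id + 1L
    }
    st$classes[[length(st$classes) + 1L]] <-
      ontology_class(id, label, synonyms = synonyms)
    for (tg in tags) {
      st$crec[[length(st$crec) + 1L]] <-
        data.frame(id = id, label = label, tag = tg,
                   stringsAsFactors = FALSE)
    }
    id
  }
  ax <- function(axiom, tag) {
    stopifnot(nzchar(tag))
    st$axioms[[length(st$axioms) + 1L]] <- axiom
    st$arec[[length(st$arec) + 1L]] <-
      data.frame(axiom = axiom_key(axiom), tag = tag,
                 stringsAsFactors = FALSE)
    invisible(NULL)
  }

  p_part <- "BFO:0000050"
  p_att <- "RO:0002371"
  p_inn <- "RO:0002005"
  p_dev <- "RO:0002202"
  properties <- list(
    object_property(p_part, "part of", is_transitive = TRUE),
    object_property(p_att, "attached to", synonyms = "attaches to"),
    object_property(p_inn, "innervated by"),
    object_property(p_dev, "develops from")
  )

  # ---- supporting vocabulary ---------------------------------------------
  muscle <- cls("muscle organ", T_VOCAB)
  mandible <- cls("mandible", T_VOCAB, synonyms = "mandible bone")
  hyoid <- cls("hyoid bone", T_VOCAB)
  stylohyal <- cls("stylohyal bone", T_VOCAB, id = "MFMO:0000053")
  tongue <- cls("tongue", T_VOCAB, id = "MFMO:0000107")
  trig_n <- cls("trigeminal nerve", T_VOCAB)
  facial_n <- cls("facial nerve", T_VOCAB)
  hypogl_n <- cls("hypoglossal nerve", T_VOCAB, id = "MFMO:0000301")
  c1_n <- cls("first cervical nerve", T_VOCAB, synonyms = "C1 nerve")
  arch1 <- cls("branchial arch 1", T_VOCAB, synonyms = "pharyngeal arch 1")
  arch2 <- cls("branchial arch 2", T_VOCAB, synonyms = "pharyngeal arch 2")

  att <- function(id, target, tag) {
    ax(ax_subclass(ce_named(id), ce_some(p_att, ce_named(target))), tag)
  }
  inn <- function(id, nerve, tag) {
    ax(ax_subclass(ce_named(id), ce_some(p_inn, ce_named(nerve))), tag)
  }
  isa <- function(id, sup, tag) {
    ax(ax_subclass(ce_named(id), ce_named(sup)), tag)
  }
  part <- function(id, whole) {
    ax(ax_subclass(ce_named(id), ce_some(p_part, ce_named(whole))), T_PART)
  }

  # a muscle on the mandible-attachment list; extra_tags marks membership
  # in the other published lists
  mandible_muscle <- function(label, extra_tags = character(0),
                              synonyms = character(0)) {
    id <- cls(label, c(T_MAND, extra_tags), synonyms = synonyms)
    isa(id, muscle, T_MAND)
    att(id, mandible, T_MAND)
    id
  }
  trig_tags <- c(T_ARCH1, T_TRIGMAND)

  # ---- muscles attached to the mandible ----------------------------------
  ant_dig <- mandible_muscle("Anterior digastric muscle", trig_tags)
  inn(ant_dig, trig_n, T_ARCH1)
  att(ant_dig, hyoid, T_PAIR)
  buccinator <- mandible_muscle("Buccinator muscle")
  dep_ang <- mandible_muscle("Depressor anguli oris muscle")
  dep_lab <- mandible_muscle("Depressor labii inferioris muscle")
  genioglossus <- mandible_muscle("Eutherian genioglossus muscle")
  geniohyoid <- mandible_muscle("Geniohyoid muscle")
  inn(geniohyoid, c1_n, T_PAIR)
  att(geniohyoid, hyoid, T_PAIR)
  lat_pter <- mandible_muscle("Lateral pterygoid muscle", trig_tags,
                              synonyms = "external pterygoid muscle")
  inn(lat_pter, trig_n, T_ARCH1)
  masseter <- mandible_muscle("Masseter muscle", trig_tags)
  inn(masseter, trig_n, T_ARCH1)
  masseter_part <- function(label, whole = masseter,
                            synonyms = character(0)) {
    id <- mandible_muscle(label, trig_tags, synonyms = synonyms)
    inn(id, trig_n, T_ARCH1)
    part(id, whole)
    id
  }
  masseter_part("Anterior masseter muscle")
  masseter_part("Deep masseter muscle")
  masseter_part("Posterior masseter muscle")
  sup_mass <- masseter_part("Superficial masseter muscle")
  masseter_part("Masseter muscle, pars reflexa", whole = sup_mass,
                synonyms = "Superficial masseter, pars reflexa")
  zm <- masseter_part("Zygomaticomandibularis muscle",
                      synonyms = "Zygomaticomandibularis")
  masseter_part("Zygomaticomandibularis muscle, infraorbital portion",
                whole = zm,
                synonyms = "Zygomaticomandibularis, infraorbital portion")
  med_pter <- mandible_muscle("Medial pterygoid muscle", trig_tags,
                              synonyms = "internal pterygoid muscle")
  inn(med_pter, trig_n, T_ARCH1)
  mentalis <- mandible_muscle("Mentalis muscle")
  mylohyoid <- mandible_muscle("Mylohyoid muscle", T_ARCH1)
  inn(mylohyoid, trig_n, T_ARCH1)
  orbic_oris <- mandible_muscle("Orbicularis oris muscle")
  platysma <- mandible_muscle("Platysma muscle")
  temporalis <- mandible_muscle("Temporalis muscle", trig_tags)
  inn(temporalis, trig_n, T_ARCH1)
  temporalis_part <- function(label) {
    id <- mandible_muscle(label, trig_tags)
    inn(id, trig_n, T_ARCH1)
    part(id, temporalis)
    id
  }
  temporalis_part("Deep temporalis muscle")
  temporalis_part("Superficial temporalis muscle")
  temporalis_part("Suprazygomatic portion of the temporalis muscle")

  # ---- digastric complex and arch-2 inference ----------------------------
  post_dig <- cls("Posterior digastric muscle", T_ARCH2)
  isa(post_dig, muscle, T_ARCH2)
  inn(post_dig, facial_n, T_ARCH2)
  orang_dig <- cls("Orangutan posterior digastric muscle",
                   c(T_MAND, T_TAXON))
  isa(orang_dig, post_dig, T_TAXON)
  att(orang_dig, mandible, T_MAND)

  # ---- trigeminal-only muscles (not on the mandible list) ----------------
  # transversus mandibulae carries the attachment the conjunction list
  # asserts for it (see the package vignette on the published-list
  # discrepancy)
  transversus <- cls("Transversus mandibulae muscle",
                     c(T_ARCH1, T_TRIGMAND))
  isa(transversus, muscle, T_ARCH1)
  inn(transversus, trig_n, T_ARCH1)
  att(transversus, mandible, T_TRIGMAND)
  for (label in c("Tensor tympani muscle", "Tensor veli palatini muscle")) {
    id <- cls(label, T_ARCH1)
    isa(id, muscle, T_ARCH1)
    inn(id, trig_n, T_ARCH1)
  }

  # ---- defined grouping class and the arch rules -------------------------
  trig_muscle <- cls("Trigeminal muscle", T_ARCH1)
  ax(ax_equivalent(trig_muscle,
                   ce_and(ce_named(muscle),
                          ce_some(p_inn, ce_named(trig_n)))), T_GROUP)
  ax(ax_subclass(ce_some(p_inn, ce_named(trig_n)),
                 ce_some(p_dev, ce_named(arch1))), T_GCI)
  ax(ax_subclass(ce_some(p_inn, ce_named(facial_n)),
                 ce_some(p_dev, ce_named(arch2))), T_GCI)

  # ---- worked logical definitions ----------------------------------------
  styloglossus <- cls("styloglossus muscle", T_DEF, id = "MFMO:0000066")
  isa(styloglossus, muscle, T_DEF)
  ax(ax_equivalent(styloglossus,
                   ce_and(ce_some(p_inn, ce_named(hypogl_n)),
                          ce_some(p_att, ce_named(stylohyal)),
                          ce_some(p_att, ce_named(tongue)))), T_DEF)
  hyoglossus <- cls("hyoglossus muscle", T_DEF, id = "MFMO:0000064")
  isa(hyoglossus, muscle, T_DEF)
  ax(ax_equivalent(hyoglossus,
                   ce_and(ce_some(p_att, ce_named(hyoid)),
                          ce_some(p_att, ce_named(tongue)),
                          ce_some(p_inn, ce_named(hypogl_n)))), T_DEF)

  # ---- detached epiphysis demonstration sub-ontology ---------------------
  epiphysis <- cls("epiphysis", T_EPI)
  digit <- cls("digit", T_EPI)
  hand <- cls("hand", T_EPI)
  phalanx <- cls("distal phalanx", T_EPI)
  epi_digit <- cls("epiphysis of digit", T_EPI)
  epi_hand <- cls("epiphysis of hand", T_EPI)
  epi_phal <- cls("epiphysis of distal phalanx", T_EPI)
  ax(ax_subclass(ce_named(digit), ce_some(p_part, ce_named(hand))), T_EPI)
  ax(ax_subclass(ce_named(phalanx), ce_some(p_part, ce_named(digit))),
     T_EPI)
  for (pair in list(list(epi_digit, digit), list(epi_hand, hand),
                    list(epi_phal, phalanx))) {
    ax(ax_equivalent(pair[[1]],
                     ce_and(ce_named(epiphysis),
                            ce_some(p_part, ce_named(pair[[2]])))), T_EPI)
  }

  ont <- ontology(st$classes, properties, st$axioms,
                  name = "feeding-muscle-fixture")
  list(
    ontology = ont,
    manifest = list(
      class_records = do.call(rbind, st$crec),
      axiom_records = do.call(rbind, st$arec)
    )
  )
}
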