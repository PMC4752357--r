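# Published competency-question answer sets, as printed: muscles attached
# to the mandible, derivatives of branchial arch 1 (the trigeminal
# muscles), and their conjunction.  Several muscles are printed under
# variant names in different lists; matching is done through
# resolve_label(), which accepts synonyms.

published_mandible_muscles <- c(
  "Anterior digastric muscle",
  "Buccinator muscle",
  "Depressor anguli oris muscle",
  "Depressor labii inferioris muscle",
  "Eutherian genioglossus muscle",
  "Geniohyoid muscle",
  "Lateral pterygoid muscle",
  "Masseter muscle",
  "Anterior masseter muscle",
  "Deep masseter muscle",
  "Posterior masseter muscle",
  "Superficial masseter muscle",
  "Masseter muscle, pars reflexa",
  "Zygomaticomandibularis muscle",
  "Zygomaticomandibularis muscle, infraorbital portion",
  "Medial pterygoid muscle",
  "Mentalis muscle",
  "Mylohyoid muscle",
  "Orangutan posterior digastric muscle",
  "Orbicularis oris muscle",
  "Platysma muscle",
  "Temporalis muscle",
  "Deep temporalis muscle",
  "Superficial temporalis muscle",
  "Suprazygomatic portion of the temporalis muscle"
)

published_arch1_muscles <- c(
  "Trigeminal muscle",
  "Anterior digastric muscle",
  "Lateral pterygoid muscle",
  "Masseter muscle",
  "Anterior masseter muscle",
  "Deep masseter muscle",
  "Posterior masseter muscle",
  "Superficial masseter muscle",
  "Superficial masseter, pars reflexa",
  "Zygomaticomandibularis muscle",
  "Zygomaticomandibularis, infraorbital portion",
  "Medial pterygoid muscle",
  "Mylohyoid muscle",
  "Temporalis muscle",
  "Deep temporalis muscle",
  "Superficial temporalis muscle",
  "Suprazygomatic portion of the temporalis muscle",
  "Transversus mandibulae muscle",
  "Tensor tympani muscle",
  "Tensor veli palatini muscle"
)

published_trigeminal_mandible_muscles <- c(
  "Anterior digastric muscle",
  "Lateral pterygoid muscle",
  "Masseter muscle",
  "Anterior masseter muscle",
  "Deep masseter muscle",
  "Posterior masseter muscle",
  "Superficial masseter muscle",
  "Superficial masseter, pars reflexa",
  "Zygomaticomandibularis muscle",
  "Zygomaticomandibularis, infraorbital portion",
  "Medial pterygoid muscle",
  "Temporalis muscle",
  "Deep temporalis muscle",
  "Superficial temporalis muscle",
  "Suprazygomatic portion of the temporalis muscle",
  "Transversus mandibulae muscle"
)

resolve_all <- function(ont, labels) {
  sort(vapply(labels, resolve_label, character(1), ont = ont,
              USE.NAMES = FALSE))
}

query_mandible <- "'muscle organ' and ('attached to' some 'mandible')"
query_arch1 <- "'muscle organ' and ('develops from' some 'branchial arch 1')"
query_trig_mandible <- paste(
  "'muscle organ' and ('innervated by' some 'trigeminal nerve')",
  "and ('attached_to' some 'mandible bone')")
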