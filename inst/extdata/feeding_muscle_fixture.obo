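format-version: 1.2
ontology: feeding-muscle-fixture

[Term]
id: MFMO:0000053
name: stylohyal bone

[Term]
id: MFMO:0000064
name: hyoglossus muscle
is_a: MFMO:0000500
intersection_of: RO:0002005 MFMO:0000301
intersection_of: RO:0002371 MFMO:0000107
intersection_of: RO:0002371 MFMO:0000502

[Term]
id: MFMO:0000066
name: styloglossus muscle
is_a: MFMO:0000500
intersection_of: RO:0002005 MFMO:0000301
intersection_of: RO:0002371 MFMO:0000053
intersection_of: RO:0002371 MFMO:0000107

[Term]
id: MFMO:0000107
name: tongue

[Term]
id: MFMO:0000301
name: hypoglossal nerve

[Term]
id: MFMO:0000500
name: muscle organ

[Term]
id: MFMO:0000501
name: mandible
synonym: "mandible bone" EXACT []

[Term]
id: MFMO:0000502
name: hyoid bone

[Term]
id: MFMO:0000503
name: trigeminal nerve

[Term]
id: MFMO:0000504
name: facial nerve

[Term]
id: MFMO:0000505
name: first cervical nerve
synonym: "C1 nerve" EXACT []

[Term]
id: MFMO:0000506
name: branchial arch 1
synonym: "pharyngeal arch 1" EXACT []

[Term]
id: MFMO:0000507
name: branchial arch 2
synonym: "pharyngeal arch 2" EXACT []

[Term]
id: MFMO:0000508
name: Anterior digastric muscle
is_a: MFMO:0000500
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501
relationship: RO:0002371 MFMO:0000502

[Term]
id: MFMO:0000509
name: Buccinator muscle
is_a: MFMO:0000500
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000510
name: Depressor anguli oris muscle
is_a: MFMO:0000500
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000511
name: Depressor labii inferioris muscle
is_a: MFMO:0000500
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000512
name: Eutherian genioglossus muscle
is_a: MFMO:0000500
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000513
name: Geniohyoid muscle
is_a: MFMO:0000500
relationship: RO:0002005 MFMO:0000505
relationship: RO:0002371 MFMO:0000501
relationship: RO:0002371 MFMO:0000502

[Term]
id: MFMO:0000514
name: Lateral pterygoid muscle
synonym: "external pterygoid muscle" EXACT []
is_a: MFMO:0000500
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000515
name: Masseter muscle
is_a: MFMO:0000500
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000516
name: Anterior masseter muscle
is_a: MFMO:0000500
relationship: BFO:0000050 MFMO:0000515
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000517
name: Deep masseter muscle
is_a: MFMO:0000500
relationship: BFO:0000050 MFMO:0000515
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000518
name: Posterior masseter muscle
is_a: MFMO:0000500
relationship: BFO:0000050 MFMO:0000515
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000519
name: Superficial masseter muscle
is_a: MFMO:0000500
relationship: BFO:0000050 MFMO:0000515
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000520
name: Masseter muscle, pars reflexa
synonym: "Superficial masseter, pars reflexa" EXACT []
is_a: MFMO:0000500
relationship: BFO:0000050 MFMO:0000519
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000521
name: Zygomaticomandibularis muscle
synonym: "Zygomaticomandibularis" EXACT []
is_a: MFMO:0000500
relationship: BFO:0000050 MFMO:0000515
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000522
name: Zygomaticomandibularis muscle, infraorbital portion
synonym: "Zygomaticomandibularis, infraorbital portion" EXACT []
is_a: MFMO:0000500
relationship: BFO:0000050 MFMO:0000521
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000523
name: Medial pterygoid muscle
synonym: "internal pterygoid muscle" EXACT []
is_a: MFMO:0000500
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000524
name: Mentalis muscle
is_a: MFMO:0000500
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000525
name: Mylohyoid muscle
is_a: MFMO:0000500
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000526
name: Orbicularis oris muscle
is_a: MFMO:0000500
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000527
name: Platysma muscle
is_a: MFMO:0000500
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000528
name: Temporalis muscle
is_a: MFMO:0000500
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000529
name: Deep temporalis muscle
is_a: MFMO:0000500
relationship: BFO:0000050 MFMO:0000528
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000530
name: Superficial temporalis muscle
is_a: MFMO:0000500
relationship: BFO:0000050 MFMO:0000528
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000531
name: Suprazygomatic portion of the temporalis muscle
is_a: MFMO:0000500
relationship: BFO:0000050 MFMO:0000528
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000532
name: Posterior digastric muscle
is_a: MFMO:0000500
relationship: RO:0002005 MFMO:0000504

[Term]
id: MFMO:0000533
name: Orangutan posterior digastric muscle
is_a: MFMO:0000532
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000534
name: Transversus mandibulae muscle
is_a: MFMO:0000500
relationship: RO:0002005 MFMO:0000503
relationship: RO:0002371 MFMO:0000501

[Term]
id: MFMO:0000535
name: Tensor tympani muscle
is_a: MFMO:0000500
relationship: RO:0002005 MFMO:0000503

[Term]
id: MFMO:0000536
name: Tensor veli palatini muscle
is_a: MFMO:0000500
relationship: RO:0002005 MFMO:0000503

[Term]
id: MFMO:0000537
name: Trigeminal muscle
intersection_of: RO:0002005 MFMO:0000503
intersection_of: MFMO:0000500

[Term]
id: MFMO:0000538
name: epiphysis

[Term]
id: MFMO:0000539
name: digit
relationship: BFO:0000050 MFMO:0000540

[Term]
id: MFMO:0000540
name: hand

[Term]
id: MFMO:0000541
name: distal phalanx
relationship: BFO:0000050 MFMO:0000539

[Term]
id: MFMO:0000542
name: epiphysis of digit
intersection_of: BFO:0000050 MFMO:0000539
intersection_of: MFMO:0000538

[Term]
id: MFMO:0000543
name: epiphysis of hand
intersection_of: BFO:0000050 MFMO:0000540
intersection_of: MFMO:0000538

[Term]
id: MFMO:0000544
name: epiphysis of distal phalanx
intersection_of: BFO:0000050 MFMO:0000541
intersection_of: MFMO:0000538

[Typedef]
id: BFO:0000050
name: part of
is_transitive: true

[Typedef]
id: RO:0002005
name: innervated by

[Typedef]
id: RO:0002202
name: develops from

[Typedef]
id: RO:0002371
name: attached to
synonym: "attaches to" EXACT []

[gci]
sub: 'innervated by' some 'facial nerve'
sup: 'develops from' some 'branchial arch 2'

[gci]
sub: 'innervated by' some 'trigeminal nerve'
sup: 'develops from' some 'branchial arch 1'
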