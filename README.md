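# tadfminer

Literature mining of photophysical properties of thermally activated delayed
fluorescence (TADF) emitters. `tadfminer` turns marked-up scientific articles
into a structured database of four molecular properties — maximum emission
wavelength λ_EM (nm), photoluminescence quantum yield PLQY (%),
singlet–triplet energy splitting ΔE_ST (eV), and delayed fluorescence
lifetime τ_D (μs) — and scores its own extraction quality with
precision/recall evaluation against gold annotations.

It is written for materials-informatics and cheminformatics researchers who
need property databases mined from article corpora, and for anyone studying
rule-based information extraction on chemistry text.

## What it implements

* **Document ingestion** for two minimal publisher-style markup dialects
  (XML-like and HTML-like), with citation/metadata blocks excluded from
  parsing and nested table headers flattened per column.
* **Sentence NLP**: lossless sentence segmentation, pluggable chemical named
  entity recognition (lexicon + morphology default), and abbreviation
  detection in which a tagged chemical name adjacent to a strictly shorter
  bracketed or equality-linked entity forms a pair — the letters-in-order
  (Schwartz–Hearst) rule is kept only for non-chemical acronyms.
* **Property ontologies** with auto-generated quantity grammars (decimals,
  ranges, powers of ten), unit normalization to fixed standard units
  (nm, %, eV, μs; kJ/mol → eV via 96.485) and Unicode homoglyph handling.
* **Sentence and table parsers**, including the cell serialization
  `headers 🙃🙃🙃🙃 cell` with first-come-first-served field capture, and
  three special table parsers: combined `ES/ET/ΔEST` columns, fractional
  PLQY values, and shared `τp/τd` lifetime cells.
* **ThemeCompound filtering**: a corpus-frequency blocklist (names in ≥
  ceil(7/1200 × corpus size) documents, counted once per document), rule
  filters for name/label shapes, an allowlist override, and forward-looking
  per-document compound resolution with a registry that resets between
  documents.
* **Post-processing**: physical-range filters (300 nm < λ_EM < 1600 nm,
  0 % ≤ PLQY ≤ 100 %, −1.5 eV < ΔE_ST < 1.5 eV, 100 ns < τ_D < 10 s),
  room-temperature standardization to 293 K, and tri-state
  experimental/theoretical classification of ΔE_ST records.
* **SMILES structure filters** that count carbons and aromatic rings
  directly on SMILES strings; molecules with < 24 carbons **and** < 5
  aromatic rings are removed from the subsidiary (SMILES-resolved) record
  set.
* **Database IO** (CSV with dotted columns / nested JSON, exact round
  trips), **evaluation** under a three-clause true-positive definition
  (property+value+unit; compound name or label; temperature for lifetimes)
  with accumulative convergence curves, and a **synthetic-corpus
  generator** that plants known facts with gold annotations so the entire
  pipeline is testable offline.

## Worked example

```r
library(tadfminer)

dir <- file.path(tempdir(), "demo-corpus")
generate_corpus(corpus_spec(n_documents = 4, seed = 7), dir)

cfg <- pipeline_config(
  lexicon = file.path(dir, "lexicon.txt"),
  threshold_fraction = 0.5,   # blocklist cut-off: ceil(0.5 * 4) = 2 documents
  smiles_backend = lookup_smiles_backend(file.path(dir, "name_smiles.tsv"))
)
res <- run_pipeline(dir, cfg)
length(res$records)
#> [1] 64

head(records_to_frame(res$records)[, c("model_name", "compound.names",
  "value", "units", "standard_value", "record_method", "temperature")], 6)
#>  model_name                                           compound.names  value units standard_value   record_method temperature
#>   lambda_em   ["8CzTRZ","1,2-Bis(carbazol-9-yl)-4,7-dicyanobenzene"]  [473]    nm          [473]        sentence
#>        plqy                                                ["3CzCN"]   [22]     %           [22]        sentence
#>  delta_e_st      ["8TzDPS","1,4-Bis(acridin-9-yl)-4,7-benzonitrile"] [0.26]    eV         [0.26]        sentence
#>       tau_d ["3TzCN","1,4-Bis(phenoxazin-9-yl)-4,5-dicyanopyridine"]  [7.9]    μs          [7.9]        sentence         300
#>   lambda_em                                               ["7PxTRZ"]  [638]    nm          [638]      table_cell
#>        plqy                                               ["7PxTRZ"] [0.83]                 [83] fractional_plqy

evaluate_records(res$records, read_records(file.path(dir, "gold.json"), "json"))
#> <tadf_evaluation_report> TP=64 FP=0 FN=0  P=1.000 R=1.000 F=1.000
```

Reading the rows: each record carries the property id, the compound (with
abbreviation-unified names — the sentence records show both the short form
and the long systematic name it was defined with), the value and unit as
found, the value converted to the property's standard unit (note the
fractional quantum yield 0.83 standardized to 83 %), the parser that emitted
it, and for delayed lifetimes the measurement temperature in kelvin. On this
noiseless synthetic corpus the pipeline recovers every planted fact exactly
(precision = recall = 1), which validates the machinery end to end; real
literature is harder and the methods vignette discusses what this result
does and does not show.

A command-line wrapper ships at
`system.file("scripts", "tadfminer.R", package = "tadfminer")` with
subcommands `extract`, `blocklist`, `evaluate` and `synth`.

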