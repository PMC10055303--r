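---
title: "Annotating sequencing-read structure with readspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating sequencing-read structure with readspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readspec)
```

## The model

A sequencing library molecule is represented as an **ordered tree of
Regions**. An atomic Region annotates one contiguous segment of the
molecule; a meta Region groups an ordered list of children whose sequences
are glued in the 5'→3' direction, so sibling order carries meaning and every
operation — traversal, serialization, indexing, rendering — preserves it.
The root document (an `assay`) carries metadata plus the ordered top-level
Regions, typically one meta Region per sequenced read.

Two controlled vocabularies close the model for validation. `region_type`
names what the segment *is* (barcode, umi, cdna, gdna, adapter, primer,
linker, fastq, Illumina adapters and indices, poly_a, named_region, other);
`named_region` and `other` keep the set extensible without abandoning a
closed enum. `sequence_type` names where the segment's sequence *comes
from*: a `fixed` literal, membership in an `onlist` (a whitelist file, one
sequence per line, optionally gzipped, with an optional md5 of the
uncompressed content), `random`, or `joined` for meta Regions. The sequence
alphabet is `{A, C, G, T, N, X}`; `X` is the unknown-base placeholder, so a
random 12-mer is written `XXXXXXXXXXXX` and remains visually distinct from
a fixed sequence in any rendering. By convention a fixed Region's sequence
length equals `min_len = max_len`, and a random Region's representative
sequence is `X` repeated `max_len` times.

Model invariants (length ordering, joined ⇔ has-children, onlist presence,
id uniqueness) are deliberately *not* enforced at construction: partially
built trees must be representable so that `init_from_newick()` and
`format_spec()` can assemble documents incrementally. Enforcement is the
job of `check_spec()`, which walks the whole tree and returns every
violation as a row (stable code, slash-delimited region-id path, message)
rather than raising on the first; a command-line `check` can then print a
complete report and exit nonzero. Unrecognized document keys are preserved
and flagged `W_UNKNOWN_KEY` (a warning, not an error) for forward
compatibility of the format; a `strict` load turns them into errors.

## Positional indexing

`index_read()` lays out a read's atomic Regions as contiguous 0-based,
half-open intervals using cumulative `max_len` offsets. Zero-length
Regions are legal and produce empty intervals (`start == end`), which lets
optional elements be modeled without restructuring the tree. A cDNA/gDNA
segment that is unbounded in practice is modeled with `max_len` equal to
the sequencer read-length remainder (the fixture default is 98 nt), so
intervals stay finite.

Variable-length Regions (`min_len != max_len`, as produced e.g. by assays
with variable-length barcodes) make downstream positions unknowable at
specification time. The index therefore carries a single flag,
`fixed_prefix_ok`: it is `TRUE` iff no variable-length interval occurs
before the final one. A lone trailing variable segment (the usual cDNA
case) is harmless — everything before it sits at a fixed offset — while a
variable segment upstream of anything else clears the flag, and every
fixed-position consumer (the technology-string emitters, FASTQ splitting,
the simulator) refuses such layouts outright rather than guessing. No
in-read anchoring or pattern search is attempted; that is a documented
non-goal, since the specification describes positional structure, not
fuzzy matching.

## Technology strings

Three preprocessing tools are supported, each with its own dialect; the
grammars are defined by this package and enforced internally by
round-tripping rather than against the external tools themselves:

* **kb** (kallisto bustools): colon-separated triples
  `<file>,<start>,<end>` with 0-based file numbers following the order in
  which read indices are supplied (which follows 5'→3' document order) —
  barcode triples, then the UMI, then the biological sequence, where
  `<file>,0,0` denotes a sequence spanning that whole read.
* **starsolo**: `--soloCBstart/--soloCBlen/--soloUMIstart/--soloUMIlen`
  with **1-based** starts (`start + 1`, `len = end − start`). The dialect
  can express exactly one fixed-length barcode and one UMI in the same
  read; split-pool layouts are rejected as unsupported rather than
  silently merged.
* **simpleaf**: per-read geometry `1{...}2{...}` built from `b[len]`,
  `u[len]`, `x[len]` (other fixed elements) and `r[len]`/`r[:]`
  descriptors, where `r[:]` is this grammar's whole-read/remainder token.

`parse_tool_string()` inverts all three (given the read lengths, which
resolve the whole-read tokens), and the test suite asserts that parsing an
emitted string recovers the original barcode/UMI/sequence intervals and
that the geometries recovered from different dialects agree wherever a
layout is expressible in all of them. This round-trip oracle is what makes
the emitters trustworthy without invoking the tools.

## Serialization

Documents are YAML with 2-space indentation. Dumps use a fixed key order
(`region_id`, `region_type`, `name`, `sequence_type`, `sequence`,
`min_len`, `max_len`, `onlist`, `regions`), making output byte-identical
across calls — a property the suite checks, since determinism is what makes
specs diffable and versionable. Onlist filenames resolve relative to the
directory containing the spec document, matching how specs and barcode
lists are distributed side by side; md5 checksums are computed on
uncompressed content so they are stable across compression settings.

## Newick initialization

`init_from_newick()` builds a skeleton from a compact tree string in which
a leaf is `id:length` and an internal node `(children)id`. The parser is a
small recursive-descent routine because the grammar repurposes the
branch-length slot for region lengths, permits single-child internal nodes
(`"(a:5)r;"`), and must report character offsets on error — none of which a
phylogenetic newick reader provides. The outermost node supplies the
assay id and becomes the single top-level meta Region. Skeleton leaves are
created fixed-length (`min = max = length`, `sequence_type = "random"`)
with `region_type` defaults of `named_region` (meta) and `other` (leaf),
intended to be edited afterwards; whether a stated length is a minimum or a
maximum for a variable region is a post-editing decision, so the skeleton
does not guess. `to_newick()` renders a topology back, and the suite
verifies init → format → check is clean and the round trip is
order-isomorphic for randomized trees.

## FASTQ splitting and verification

`split_fastq()` slices each record's sequence and quality strings
identically at the interval boundaries, suffixes headers with
`/<region_id>`, and writes one output per atomic Region (per-meta-region
grouping was considered and rejected as lossier; atomic outputs can always
be re-joined). Records shorter than the fixed prefix are skipped and
counted, never fatal; a residual length outside the final Region's bounds
is counted as a violation but the record is still split, so concatenating
the slices always reproduces the surviving records byte-for-byte.
`verify_reads()` counts fixed-sequence mismatches (exact, with `N` in a
read matching any base), onlist misses (exact membership) and length
violations.

## What the fixtures emulate — and what they do not

`make_spec()` generates four layouts: a droplet-style geometry (16-nt
onlist barcode + 12-nt UMI on read 1, cDNA on read 2), a split-pool
geometry (three 8-nt barcode rounds with separate onlists, 6-nt fixed
linkers, 10-nt UMI), the canonical adapter–insert–adapter construct (whose
variable middle insert deliberately exercises the refusal paths), and
randomized nested trees for structural properties. Onlists are random
*distinct* fixed-length sequences, 100 per file by default — small enough
to regenerate instantly, large enough that an accidental membership of a
random corruption is effectively impossible (and the simulator resamples
to exclude it outright).

`simulate_reads()` draws records by concatenating per-Region sequences and
applies corruptions per record with the configured probabilities, logging
exactly which records it corrupted. That ledger is the oracle for
verification: at corruption rate 0 every count must be zero, and at any
rate the verifier's counts must equal the ledger exactly, per region and
per kind. Everything is deterministic under the configured seed, down to
bytes.

The simulator emulates *structure*, not sequencer physics: qualities are
constant, substitutions replace whole segments rather than following
quality-dependent error profiles, and there are no indels, chimeras or PCR
duplicates. Passing tests therefore demonstrate that the positional logic,
serialization and accounting are exact — they do not demonstrate robustness
to real-world error modes, which positional splitting by design does not
attempt to absorb.

## Problem sizes and numerical choices

The property suites use 100 randomized trees for serialization and
formatting, 50 random newick strings, all four layouts for indexing and
rendering equivalence, and 10,000 simulated reads for split/rejoin
exactness — sizes at which every property is exercised across hundreds of
distinct shapes while the full suite runs in seconds. All quantities are
integer nucleotide counts, so every comparison in the package and its tests
is exact equality; there are no floating-point tolerances anywhere.

## Known limitations

Barcode error correction, onlist construction from data, spec inference
from FASTQ, fuzzy adapter trimming and demultiplexing by barcode value are
out of scope. The technology-string dialects cover three tools; adding a
dialect means writing an emitter/parser pair that satisfies the same
round-trip property. HTML output is a minimal wrapper around the markdown
table, not a styled report.
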