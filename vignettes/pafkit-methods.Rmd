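---
title: "pafkit: conventions, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pafkit: conventions, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafkit)
```

`pafkit` manipulates pairwise alignments in PAF format without ever letting a
coordinate and its CIGAR drift apart. This vignette records the conventions
the package commits to, how each algorithm works, why the defaults are what
they are, and what the synthetic fixtures do and do not demonstrate.

## Coordinate and CIGAR conventions

Everything is 0-based, half-open, on both axes — the native convention of PAF
and BED. Query coordinates are always reported on the query's forward strand.

CIGARs use the `minimap2 --eqx` alphabet: `=` match, `X` mismatch, `I`
insertion (query-only bases), `D` deletion (target-only bases). The ambiguous
`M` is accepted by the parser — real-world files contain it — but rejected by
every identity computation with an error advising `--eqx` input, because an
`M` column cannot be attributed to a match or a mismatch.

The CIGAR is stored in **target-forward order**. For a `-` strand record the
query is walked from high to low forward-strand coordinates. This matches how
minimap2 emits PAF and has a useful consequence: all target-space operations
are strand-agnostic, and a strand flip is a pure coordinate reflection
(`qstart' = qlen − qend`) that leaves the CIGAR untouched.

Two invariants are enforced on every record the package builds or parses:
the CIGAR's consumed lengths equal the coordinate spans on both axes, and a
record never starts or ends in an indel. The second rule ("no dangling
indels") is what makes trimming well-defined: an unaligned base at a record
edge carries no positional information.

### cs difference strings

The `cs` tag is richer than the CIGAR (it carries the actual substituted and
inserted/deleted bases), so the package avoids emitting a stale one. Because
cs tokens correspond one-to-one with CIGAR columns in walking order, any
sub-alignment extraction can cut the cs string in lock-step by column counts,
and `pafkit` does so. Edits that change the meaning of the token payloads —
query/target inversion, strand flipping — drop the tag with a logged message
instead. Dropping information was judged safer than re-deriving sequence
content we do not have.

## Sub-alignment extraction

`subalignment_by_target()` / `subalignment_by_query()` are the single source
of truth for every trimming operation in the package (liftover, overlap
resolution, splitting). The requested window is intersected with the record,
cut at run boundaries, and then shrunk so the result begins and ends on an
aligned column. Two boundary rules follow:

* a boundary inside a deletion moves inward to the nearest aligned base;
* an end is never extended into an insertion — the record stops at the last
  aligned base. Block-based liftover implementations that place the end
  coordinate one base into the insertion will report an end exactly 1 bp
  further; the 1-bp discrepancy is reproduced by a dedicated test fixture.

The whole module is checked against an exhaustive oracle: expanding a record
into per-base columns (`aligned_columns()`), clipping the columns to the
window, and re-encoding. The oracle is O(alignment length) per call and only
used for verification; the production path is O(number of runs).

## Overlap resolution (`trim_paf`)

Overlapping query alignments are resolved by cumulative-score maximization.
For a pair overlapping on `[olo, ohi)` the algorithm charges every column of
each record to a forward-strand query position — matches and mismatches and
insertions at their own position, each deletion at the position of the next
aligned column in walking order — and picks the split
`p* = argmax F_left(p) + S_right(p)` with `F`/`S` prefix and suffix sums over
the overlap. Charging deletions forward keeps the sums well-defined over
query coordinates and means a split can never land inside a deletion. Ties
go to the smallest `p`, so results are deterministic.

Default scores are `match = +1`, `mismatch = −1`, `indel base = −1`; there is
a single per-base indel score rather than separate open/extend penalties
(nothing in the workflow needs affine gaps — the split only compares which
record aligns the contested bases better). All three are exposed as
parameters and CLI flags.

The driver repeatedly resolves the *largest* remaining overlap and recomputes
overlaps after every trim, since spans change; records whose retained span
has no aligned column are dropped. The loop terminates because each
iteration removes its pair's overlap entirely, and the fixed point (pairwise
disjoint query intervals per query name) makes the operation idempotent.

**Limitation — containment.** When one record's query span strictly contains
the other's, the uniform rule (left record keeps `[qstart, p*)`, right
record keeps `[p*, qend)`) sacrifices the outer record's tail beyond the
overlap: records are contiguous and cannot keep two disjoint pieces. The
inner record can still end up trimmed on both sides, or dropped, across
iterations when several records chain. Strict containment between otherwise
disjoint alignments is rare in practice (supplemental alignments at
duplications overlap at their edges), but users with pathological inputs
should split records first (`break_paf`) so the machinery sees edge
overlaps.

## Splitting at structural variants (`break_paf`)

Records are cut at every `I`/`D` run whose length **strictly exceeds** the
threshold ("exceeding" is read literally, so a run of exactly the threshold
survives). Only single runs are compared against the threshold; mixed
adjacent indels are not summed. Each segment between cuts is rebuilt by the
same sub-range machinery, so a sub-threshold indel stranded at a new segment
edge is trimmed off too, and every segment carries a provenance tag
`id:Z:{record}.{segment}` (1-based). Aligned columns are conserved exactly:
the only bases lost are those of the removed indels and of edge-stranded
indels, none of which were aligned.

## Orientation and pseudo-scaffolds

`orient()` compares query-consuming aligned bases (`qend − qstart` summed per
record) between strands for each query and flips the whole query when
reverse strictly exceeds forward; an exact tie keeps the original
orientation, for determinism. Flipped contigs are *not* renamed — the name
is an identifier for sequence retrieval, and a silent rename would break
joins against FASTA indices.

`scaffold()` assigns each query wholly to the target with the most aligned
bases (a contig must live at one scaffold position), orders contigs by
minimum target start (ties: name), and offsets them into a
`{tname}_scaffold` coordinate system with a spacer gap between contigs. The
default gap of 1,000 bases is an arbitrary but conventional spacer size of
the kind used in scaffolding pipelines; it is configurable and does not
affect any statistic, since only names and offsets change — a property the
tests assert bit-exactly.

## Identity statistics

The three reported identities differ only in the denominator:

| statistic | denominator |
|---|---|
| `perID_by_matches` | `m + x` |
| `perID_by_events`  | `m + x + #I ops + #D ops` |
| `perID_by_all`     | `m + x + I bases + D bases` |

with `m` matched, `x` mismatched bases. The denominators are nested, so the
three values are ordered on every record; all three equal 100 only for a
gap- and mismatch-free alignment. Degenerate records with no aligned column
emit a row of zeros with a warning rather than aborting a stream — a
mid-pipeline crash on one pathological record would be worse than a flagged
zero. Percentages are printed with four decimal places so text outputs are
stable under diffing.

## The synthetic generator and what the tests show

`simulate_alignment()` builds records directly from an event list — no
sequence is synthesized and no aligner runs. A tandem duplication is modeled
from the query's perspective as a *collapsed* duplication: the target carries
two adjacent copies, the query one, so the single query copy aligns to both
target copies through two records overlapping in query coordinates — exactly
the supplemental-alignment pattern overlap trimming exists for. Inversions
become separate `-` strand records; substitutions are planted per base at a
configurable rate in plain regions only, and every planted edit is recorded,
which is what makes the statistics checks exact rather than approximate.

Default study conditions used by the test-scale scenarios: targets of 4–50 kb
for property tests and 1 Mb for the end-to-end pipeline run, substitution
rates of 0.5–3 %, indels up to 10 kb, duplication/inversion blocks of
0.05–5 kb — sizes chosen to exercise every code path (including the 1,000 and
5,000 bp splitting thresholds and the 100 kb pair filter) while keeping the
whole suite in a few minutes on one core.

What passing these tests does *not* show: the generator emits clean,
non-contradictory alignments. Real aligner output contains `M` ops, clipped
and low-quality records, overlapping alignments that disagree about the
homology (not just about its copy), and cs tags with genuine sequence
content. The parser and the statistics handle these defensively (errors and
warnings, not silent corruption), but the truth-map guarantees apply to the
simulated regime only.

## Numerical and degenerate-input choices

* All coordinates are integers; scores are doubles but sums over integer
  per-base scores are exact, so split ties are true ties and the smallest-`p`
  rule is the only tie-breaker in the package.
* Empty input is legal everywhere and yields empty output (the CLI exits 0).
* A liftover interval entirely inside a deletion has no aligned column and
  is skipped with a counted message; a window request outside a record's
  span returns the empty-result signal (`NULL`), not an error.
* `mapq` is carried through unchanged by every edit; `nmatch` and `alnlen`
  are always recomputed from the edited CIGAR.
* The ribbon plot builds its SVG as plain text with fixed-width number
  formatting, so identical input produces byte-identical output; opacity is
  an affine map from `[min displayed identity, 100]` onto `[0.2, 1.0]`
  (fully transparent ribbons would vanish), with forward/reverse fixed to
  `#3b6fb6`/`#e07b39`.

## Known limitations

* No BAM/SAM ingress or egress; PAF (and BED) only.
* No chain-file liftover and no multi-hop projection across two alignments.
* Containment behavior of `trim_paf` as described above.
* The plotter is intentionally static: no interactivity, zooming or hosted
  views; one target region per figure, queries laid out side by side.
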