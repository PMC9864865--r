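---
title: "Length-based QC of chloroplast genome assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-based QC of chloroplast genome assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenqc)
```

## The idea

Complete chloroplast genomes (plastomes) of flowering plants are mostly
120–170 kbp long, and within a genus their lengths are usually remarkably
uniform — often within a couple of hundred base pairs of the genus median.
That tightness makes sequence *length*, a field present in every database
summary record, a cheap but informative QC signal: a record tens of
kilobases away from its genus's typical length is either biologically
remarkable (loss or expansion of the inverted repeat, parasitic reduction,
a polyphyletic genus) or simply mis-assembled.

`lenqc` operationalizes this in four stages, working purely on summary
metadata (no sequences are ever downloaded):

1. **Acquisition** — summary records (accession, organism, taxid, length,
   publication date, source database) are pulled through a pluggable
   *summary source*; lineage (genus/family/informal clade) comes from a
   taxonomy table.
2. **Distribution assessment** — per family and per genus, the length
   sample is reduced to boxplot descriptors: median, quartiles, IQR,
   Tukey fences at $q_1 - k\,\mathrm{IQR}$ and $q_3 + k\,\mathrm{IQR}$
   with $k = 1.5$, and the width statistic
   $100 \cdot \mathrm{IQR}/\mathrm{median}$ (in percent). Only families
   with at least 20 and genera with at least 10 records are assessed —
   below that, quartiles of such narrow distributions are too noisy to
   act on.
3. **Wide filtering** — taxa whose IQR/median ratio strictly exceeds a
   threshold (1% for genera, 10% for families by default) are flagged as
   *wide*; wide families are decomposed into their largest genera (up to
   six, each with more than one sequence) to locate the source of the
   spread.
4. **Outlier QC** — records strictly outside the genus fences are
   outliers. For each outlier species the GenBank side of the source is
   queried; records identical to the flagged one are removed, and if some
   remaining *alternative* is strictly closer to the genus median, the
   flagged assembly — not the species — is the likely anomaly.

## Statistical choices

**Quantile convention.** Quartiles use linear interpolation at index
$p(n-1)$ on the sorted sample (R's type 7, the default of the common
Python plotting stack). The choice is visible at small $n$: for
$(140000, 150000, 160000)$ it gives $q_1 = 145000$, $q_3 = 155000$, hence
IQR $= 10000$ and fences $130000/170000$. Other conventions can be
selected via the `type` argument of `length_quantile()` and
`compute_boxplot_stats()`, but should be fixed once per analysis; all
worked examples and tests in this package use type 7.

**Arithmetic fences.** The fences are the pure Tukey values, not snapped
to the most extreme in-fence observation. Snapping affects only how
whiskers are *drawn*; outlier calls depend on fence placement, and the
arithmetic reading keeps them a deterministic function of the quartiles.

**Strict inequalities everywhere.** A record exactly on a fence is not an
outlier; a ratio exactly at the wideness threshold is not wide; an
alternative at exactly the outlier's distance is not closer. Ties
therefore never flag. The boundary rule is exposed (not buried) so its
effect can be audited.

**Zero-spread samples.** If IQR $= 0$ the ratio is 0 and both fences
collapse onto the common value, so no member can be *strictly* outside:
constant genera produce no outliers by construction.

**Multiple records per species** all enter the genus sample
independently; distributions count sequences, not species.

**Identical-record removal.** RefSeq is drawn from GenBank, so the
species-level GenBank query always returns the flagged record's own
lineage-mates. Without sequences, two desk-scale proxies identify "the
same assembly": a shared accession stem, and exact length equality. The
number removed is reported (`n_identical`) so users can audit the proxy;
a same-length independent assembly would be removed too, which is
conservative for the closer-than test.

**Best-candidate tie-breaks.** Among alternatives the *best* is the one
with minimal $|{\rm length} - {\rm median}|$; ties break by earliest
publication date (older records have had more scrutiny), then by
accession for full determinism. Because counting "species with any closer
alternative" and "species whose best candidate is closer" can differ, the
assessment reports both `closer` (best candidate) and `any_closer`.

**Genus median including the outlier.** The median used in the
closer-than comparison is that of the full genus sample — the same
`compute_boxplot_stats()` output the fences came from. With the genus
minimum of 10 records a single outlier barely moves the median, and
reusing one set of descriptors keeps every stage consistent.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_family_n` | 20 | records | family quartiles stable enough to act on |
| `min_genus_n` | 10 | records | genus quartiles stable enough to act on |
| `wide_family_pct` | 10 | % IQR/median | families aggregate several genera, so more spread is normal |
| `wide_genus_pct` | 1 | % IQR/median | within-genus spreads are empirically far below 1% |
| `whisker_k` | 1.5 | × IQR | the standard Tukey multiplier |
| `max_genera` | 6 | genera | keeps family decomposition plots readable |

## The synthetic fixture generator

Offline testing needs data whose anomalies are known. `generate_fixture()`
draws each genus's lengths from a normal law around a typical plastome
center (120–170 kbp), with a default within-genus standard deviation of
150 bp — chosen to emulate the empirically very tight within-genus
spreads (half of real genera keep most members within ~200 bp of the
median). Three regimes cover the structures seen in real data:

* `narrow` — the plain normal law;
* `wide_parasite` — the standard deviation is multiplied (default ×20,
  i.e. 3 kbp) so the expected IQR/median ratio lands well above the 1%
  genus threshold, emulating the broad length variation of strongly
  reduced parasite plastomes;
* `ir_loss_shift` — a random subset of members (probability 0.4, at
  least one) is shifted down by 25 kbp, one inverted-repeat copy,
  producing the bimodal samples that IR loss creates.

Mis-assembly is emulated by *injected outliers*: signed offsets (default
magnitude 25 kbp, an IR-copy-scale error consistent with the real
discrepancies in the curated examples, −25.8 kbp and +71 kbp) added to
otherwise-typical members and recorded in the ground truth. The GenBank
mirror then contains one identical-length duplicate per record (the
pre-RefSeq submission) and, with configurable probability, a "corrected"
alternative drawn within one standard deviation of the genus's
clean-member median.

What the generator deliberately does **not** emulate: heavy-tailed or
skewed within-genus length laws, taxonomically misassigned records,
polyphyletic genera (wide without any assembly error), partial genomes
labelled complete, or correlated submission batches. Passing the
recovery tests therefore shows the machinery is correct and well
calibrated under idealized narrow-normal conditions — not that real
RefSeq snapshots will show the same sensitivity/specificity.

The reference fixture (`default_fixture_specs()`) holds 161 records in
seven genera and five families across both informal clades: four clean
narrow genera (two carrying one ±25 kbp injected record each), one
parasite-regime genus of 20, one IR-loss genus of 12 (whose family, at 12
records, falls below the family minimum — exercising the skip path), and
one genus of 9 that falls below the genus minimum.

## Numerical and engineering notes

* Determinism is contractual: fixtures are generated under
  `withr::with_seed`, every tie-break is total, and two pipeline runs on
  the same fixture produce byte-identical TSV output (hash-checked in the
  tests).
* Degenerate inputs: empty samples are domain errors; non-positive
  lengths are validation errors at table ingestion (rejected per row with
  diagnostics, not silently); records lacking a genus or family are
  excluded from that rank and tallied in the skip log.
* Accession uniqueness is enforced on the unversioned stem within a
  source database, so re-versioned records cannot appear twice.
* The report workbook is the single-file XML Spreadsheet 2003 format:
  plain text, named worksheets (`RefSeq`, `Distributions`, `WideAll`,
  `WideFamilies`, `WideGenera`, `Outliers`, `Alternatives`), numeric
  cells at full precision with display styles (thousands separators,
  two-decimal ratios) so formatting never loses data. TSV mirrors are
  written alongside.
* Problem sizes in the tests and the acceptance script: oracle
  equivalence runs 1000 random samples of $n \in [2, 200]$; power checks
  use 50 fixture seeds per condition (genera of 20–30 records). These
  sizes give stable rates while keeping a full run around a minute.

## Known limitations

* The closer-than verdict is purely length-based; a "closer" alternative
  can still be a bad assembly of the right length, and a genuinely
  divergent plastome (parasite, IR loss) will look like an outlier
  forever. The verdict flags records for *closer examination*, it does
  not correct them.
* Wideness attribution (parasitism, IR dynamics, polyphyly) is user
  knowledge, not computed — the pipeline only measures spread.
* The identical-record proxy (length equality) cannot distinguish a
  re-submission from an independent assembly that happens to match
  exactly.
* The remote NCBI backend is a thin convenience for interactive use; all
  validated behavior is defined against the offline fixture backend.
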