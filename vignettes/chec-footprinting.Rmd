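---
title: "Modeling in vivo ChEC footprints at yeast subtelomere-telomere junctions"
author: "telochec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling in vivo ChEC footprints at yeast subtelomere-telomere junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telochec)
```

# The measurement being modeled

In vivo ChEC maps protein-DNA organization by fusing the catalytic
domain of micrococcal nuclease (MN) to a carrier protein and inducing
cleavage with calcium in permeabilized cells. Genomic DNA is then cut
with a restriction enzyme, separated on an agarose gel, blotted, and
probed with a fragment that abuts one restriction cut. Because the probe
is anchored, every sub-full-length band corresponds to an MNase cut at
an offset from the anchor equal to the band's size (indirect
end-labeling), as long as digestion is partial enough that the single
cut nearest the anchor dominates.

`telochec` implements both directions of this experiment: a forward
simulator that turns a ground-truth occupancy map into per-lane fragment
populations and virtual blot profiles, and the inverse pipeline (band
calling, sizing, consolidation, interval classification, model
reconstruction) that the original analysis performed on real blots. The
package's templates encode the restriction fragments analyzed at
*S. cerevisiae* chromosome ends: the generic terminal Y' fragment, two
terminal X fragments (TEL03L, TEL06R), two internal X-Y' junction
fragments (TEL05R, TEL16R), the TRP1ARS1 replication-origin control, and
a plasmid-borne copy of the TEL05R X-Y' junction.

# Templates and ground truth

A `SubtelomereTemplate` uses 0-based half-open offsets from the
probe-proximal restriction cut, increasing toward the telomere (or the
distal restriction cut on internal fragments). Coordinates printed in
the original report - the TEL03L site IV at 804 bp and its Abf1 site at
783 bp from the HindIII cut, the X(TEL05R) ACS at 1325 bp and Abf1 at
1545 bp from the PvuI cut, the conserved 221 +/- 1 bp ACS-Abf1 spacing of
X-only telomeres, the 143 +/- 9, 152 +/- 12, 187 +/- 16, 106 +/- 15 and
129 +/- 11 bp inter-site spacings, the Y'-I sites 70 +/- 20 and 65 +/- 4 bp
beyond the X-Y' junctions - are encoded as `published` features and
site positions. Positions shown only graphically are chained from those
printed anchors and flagged `reconstructed`; they are template
parameters, not constants the tests assert against external values.

Each template plants a narrow accessible window (half-width 8 bp; 3 bp
where a 146-bp nucleosome fits a 152-bp interval exactly) at every
preferential cut site, and fills all remaining DNA with protein
footprints: nucleosomes of exactly 146 bp, a 41-bp ORC centered on each
ACS (midpoint of the 38-44 bp range measured in vitro), 16-bp Abf1
blocks, and Tbf1/Reb1 blocks as general-regulatory-factor filler. The
unmapped probe-proximal approach of each fragment is modeled as a
continuous nucleosome array with no accessible linkers: those linker
positions were never read out on the blots, so the generator does not
invent sites there. Terminal templates end in a telomeric tract drawn
per molecule from Normal(300, 75) bp truncated to +/- 2 SD, covered by a
Rap1 array.

Occupant protections (the fraction by which the cut rate is suppressed
inside a footprint) default to 0.995 for nucleosomes, 0.99 for
single-factor footprints, and 0.998 for the Rap1-covered tract. These
are deliberately tight: on a kilobase-scale fragment, the cumulative
leakage hazard of the occupied approach competes with the planted
windows, and looser values (e.g. 0.98 per nucleosome) turn crisp
partial-digest lanes into smears with spurious truncation peaks, which
is not what the source blots look like. The one deliberate exception is
the TEL06R junction interval, filled at protection 0.9 to express its
documented poorly-protected, diffusely cut character. All protections
are arguments of `buildTemplate()`.

The short protected interval distal to the Y'-ACS is genuinely ambiguous
in the source data (ORC alone versus ORC plus another factor), so
`buildTemplate("YpTRF", yprimeVariant = )` provides both ground truths:
`"factor"` (default) plants an unknown non-histone factor; `"orc_only"`
leaves a weakly protected, unstable particle.

# The digestion model

Cuts are an inhomogeneous Poisson process with per-bp mean

```
k * a(x) * c(x) * temperatureFactor * time
```

* `k` (`baseRate`, cuts per accessible bp per minute at 30 C, default
  0.025) is calibrated so that a typical 16-bp accessible linker is
  near-certainly cut within 5 min at 30 C - the complete-digestion
  regime of the histone fusion.
* `a(x)` is 1 on free DNA and `1 - protection` inside footprints.
* `c(x)` is the relative local concentration of the fusion. Free
  constructs (GBD-MN, NLS-MN) have `c = 1` everywhere. A tethered
  construct has a small untethered pool (`floor`) scaled up by box
  kernels around its anchors: `c(x) = floor * (1 + sum lambda_i K_i)`.
  MN-Rap1 (floor 0.005, lambda 600) anchors at annotated Rap1 sites
  (reach 185 bp) and at the telomeric tract; H2A-MN (floor 0.15, lambda
  8) anchors at every nucleosome with reach 146 bp - one core - which
  makes its coverage exactly uniform over abutting arrays; Yku70-MN
  anchors at the physical DNA end.
* `temperatureFactor` is 1 at 30 C and 0.05 on ice, encoding the
  observation that 15 min at 4 C resembles 1 min at 30 C.

The telomeric tract is an extended Rap1-covered source, not a point
site, so its kernel has two tiers: full amplitude over the mean tract
plus the construct's reach (the near field), and one tenth of the
amplitude out to 500 bp (the far field). The near field makes the
junction site the dominant early MN-Rap1 cut; the far field is what
renders the ACS-flanking sites two-to-three hundred bp into the
subtelomere visible to MN-Rap1 at all, so that the junction
accessibility ratio I/(II+III) is computable for every construct. The
choice of a multiplicative enhancement (scaling the fusion's own small
free pool rather than adding to a unit background) reflects how a
sequestered fusion behaves: away from its anchors it cuts late and
weakly, which is also what makes the fold-back experiment's predicted
loss of cleavage expressible.

Restriction cuts at the declared `restriction_site` features bound every
molecule; fragments overlapping the probe are the detected population.
Every lane draws its random stream from a seed derived from the master
seed and the lane identity by a 31-bit polynomial rolling hash
(`laneSeed()`), so lanes are reproducible individually and independent
of simulation order.

The default experiment (`defaultLaneDesign()`) samples 1, 2 and 5 min at
30 C and 2, 5 and 15 min on ice: the very partial on-ice digests are
required to read out sites distant from the probe, because at 30 C the
first-cut competition of proximal sites starves distal bands.

# The virtual blot and the inverse pipeline

Fragments migrate by `m(s) = a - b log10(s)`; the fixture ladder spans
0.1-10 kb and the default calibration is its exact least-squares fit
(`a = 100`, `b = 30`). Each fragment contributes a unit-area Gaussian of
width `bandSigma` (default 0.25 profile units, resolving bands 8% apart
in size at four sigma - enough to separate an 85-bp doublet at 1.3 kb,
and comfortably more than the 20% resolution the analysis minimally
needs). Probe detection is count-proportional: one hybridization event
per fragment, regardless of length.

Band calling finds local maxima with topographic prominence of at least
5% of the lane maximum (3% for H2A-MN on-ice lanes, whose cutting is
deliberately very partial), excludes the uncut input band (for terminal
fragments, everything beyond the junction plus 100 bp, since the
full-length band is a tract-length smear), excludes bands smaller than
the probe (end-point mono-nucleosomal products cannot be read as
anchored cut sites), and applies an absolute detection limit of 1% of
total lane signal - the blot-exposure floor below which a band is not
scorable. H2A-MN lanes contribute sites only from the 4 C regime; its
30 C lanes run to complete digestion and carry ladder products rather
than site information.

Cut offsets pooled over lanes are consolidated by single-linkage
clustering with a 25-bp tolerance (implemented as gap-splitting on the
sorted offsets, which is exactly single linkage in one dimension). A
cluster must be supported by at least two lanes to be reported as a
preferential site, mirroring the original requirement of at least two
independent experiments; clusters are labeled with Roman numerals from
the junction inward on terminal fragments (site I nearest the telomere,
as on the blots) and ascending with region prefixes (S-, X-, Y'-) on
internal fragments.

Intervals between consecutive sites are classified by the 146-bp rule -
146 bp is the minimal nucleosome footprint, so an interval of exactly
146 bp is `nucleosome_compatible` and anything shorter is
`sub_nucleosomal` - with SDs propagated from the flanking sites in
quadrature. Feature association requires the feature center to lie at
least 10 bp inside the interval (precedence ORC/ACS, then Abf1, then a
Tbf1/Reb1 array of at least two sites); the junction-proximal interval
of a terminal fragment that is GRF-held or sub-nucleosomal reconstructs
as a GRF-bound nucleosome-free region. An internal X-Y' boundary is not
a physical DNA end and never counts as junction-proximal.

# The fold-back experiment

`foldbackTest()` simulates the MN-Rap1 pattern on the TEL05R X-Y'
junction under two hypotheses. Under direct binding, the fusion anchors
at the X element's own Rap1 sites in every genotype and context. Under
the fold-back hypothesis, the enhancement over the X element is
delivered by terminal telomeric Rap1 through a SIR/yKu-dependent loop,
so it exists only for a wild-type chromosomal locus; in sir or yku80
deletions, or on a plasmid carrying no telomeric repeats, the fusion has
no anchor on the fragment and only its free pool remains - below the
detection limit within the sampled time course. Conditions are compared
to the wild-type chromosomal reference of the same mode by a
matched-site L1 divergence on percent signal, with unmatched sites
contributing their full signal as penalty (the original comparison was
by eye; this is its operationalization).

# PWM scanning

Binding-site annotation uses log-odds matrices built from count matrices
with a total pseudocount of 0.8 split by background (uniform by
default), and exact p-values computed by convolving the per-column score
distributions on a rounded grid (granularity 0.01 bits; the grid error
is bounded by motif length times granularity). Thresholds are bound to
matrix identity: p < 0.001 for the Rap1, Reb1 and Abf1 matrices, 0.005
for Tbf1, 1e-6 for the ACS weight matrix. The bundled matrices are
small synthetic fixtures labeled with the corresponding JASPAR
accessions, built around each factor's canonical consensus; they are
adequate for planting and recovering motifs on synthesized template
sequences, but genome-scale site counts obtained with them are not
comparable to scans with the curated matrices.

# What the generator does and does not emulate

It emulates: partial-digestion kinetics over a time course at two
temperature regimes; construct-specific delivery (free, telomere-bound,
histone-incorporated, end-bound); heterogeneous telomeric tract lengths
and the resulting full-length smear; count-proportional probe detection;
log-linear migration with band broadening; detection limits; and the
consolidation arithmetic of the original analysis.

It does not emulate: MNase sequence preference (cutting is
sequence-blind within accessible DNA), digitonin permeabilization
efficiency, probe hybridization kinetics, cross-hybridizing bands,
membrane stripping, 2-D gel-image artifacts, gel-top band compression,
or cell-cycle variation in occupancy. Passing tests therefore show that
the inverse pipeline correctly inverts this forward model at realistic
signal levels - not that the model captures every feature of real
blots. Band intensities and ratio magnitudes depend on unmeasured
kinetic constants, so only their orderings are meaningful.

# Problem sizes and numerical choices

Simulated experiments use 2000 molecules per lane (six lanes per
construct, four constructs); property suites that iterate over many
seeds scale down to 500-1200 molecules. The virtual gel uses an axis
step of 0.05 profile units. Ties in clustering are resolved by the
sorted-gap construction (an observation joins the chain it is within
tolerance of); observations exactly on a region boundary keep their
arithmetic side, and X-element site counting allows a 20-bp slack at the
element start because a consolidated mean can drift a few bp across an
annotated boundary when its cut window straddles it. Degenerate inputs
(empty lanes, flat profiles, single sites, missing denominators) return
empty results or flagged values rather than errors; detection-limited
ratios are reported as flagged, never as numbers.
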