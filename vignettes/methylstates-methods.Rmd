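---
title: "Calling methylation states on BeadChip arrays: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling methylation states on BeadChip arrays: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Illumina HM450K and EPIC arrays report a beta-value per CpG probe — the
fraction of methylated signal, in [0, 1].  Genome-wide, beta-values are
bimodal (an unmethylated and a methylated peak), and neighbouring CpGs
are strongly correlated: methylation is organized in domains, not at
isolated sites.  Fixed thresholds (e.g. "< 0.2 is unmethylated") ignore
both facts and transfer poorly between cell types whose global
methylation levels differ.  `methylstates` instead labels sites and
regions by decoding a hidden Markov model along each chromosome, so the
thresholds separating un-, middle- and full-methylated material are
effectively learned from each sample.

## The two-layer two-state model

For one chromosome, the observation sequence $O = \{o_1, \dots, o_k\}$
is the beta-values of its probes in genomic order, and the hidden
sequence $H = \{h_1, \dots, h_k\}$ takes the two values
$L_{me}$ (low-methyl) and $H_{me}$ (high-methyl).  The joint
probability is the usual HMM factorization

$$P(O, H) = P(h_1)\,P(o_1 \mid h_1)\prod_{i=2}^{k}
  P(h_i \mid h_{i-1})\,P(o_i \mid h_i),$$

with emissions modelled as normal densities truncated to the beta-value
support:

$$o_i \mid h_i = s \;\sim\; \mathrm{TN}(\mu_s, \theta_s^2)\ \text{on}\ [0,1].$$

Initialization is empirical: sites are split at a beta cutoff of 0.6
(low iff $o_i \le 0.6$), the transition matrix is the pseudocounted
frequency of state changes between adjacent sites, and each state's
$(\mu, \theta)$ are the moments of its group.  Parameters are then
refined by Baum-Welch and the state path decoded by Viterbi, all in log
space.  Chromosomes are separate chains sharing one parameter set —
spatial correlation is an argument along a chromosome, and chaining
chromosome ends together would fabricate adjacency.

The two-state split alone cannot produce the middle-methylated
category.  The second layer supplies it: for each decoded class, the
package tests whether the class's beta distribution is bimodal.  If it
is, the same two-state machinery is re-run on just that class's sites
(re-chained in genomic order per chromosome, initialization cutoff at
the class median — the global 0.6 is meaningless inside a one-sided
class), and the sub-state with the smaller fitted emission mean takes
the lower label: the low class splits into UMS/MMS, the high class into
MMS/FMS.  A unimodal class maps wholesale to UMS (low) or FMS (high).
Middle calls from both classes share the single MMS label.

### Why the emission M-step is guarded

The textbook M-step for normal emissions — responsibility-weighted mean
and standard deviation — ignores truncation.  With emission means near
0.1/0.9 and spreads below 0.15 the bias is negligible, but when a mean
sits very close to 0 or 1 the moment update can *decrease* the
likelihood, and a non-decreasing trace is one of the package's tested
guarantees.  The update is therefore a generalized EM step: the moment
estimate is accepted when it improves the responsibility-weighted
truncated-normal log-likelihood, otherwise a Nelder-Mead refinement is
run, and a losing update is never accepted.  Emission standard
deviations are floored at `sigma_floor` (default 1e-3) so a state can
never collapse onto a point mass.

### The bimodality gate

The gate decides whether a class is split again, a decision the rest of
the pipeline inherits, so it should be assumption-light.  The default
is Hartigan's dip statistic — the sup-norm distance between the
empirical cdf and the nearest unimodal distribution function — computed
exactly by a convex-hull sweep over candidate modes with a bisection
refinement for the (rare but real) configurations where the convex and
concave branches' values at the mode constrain each other.  P-values
come from a precomputed table of null quantiles under uniform samples
(the classical least-favourable unimodal null; 999 replicates per
tabulated sample size, regenerable with `tools/make-dip-table.R`),
interpolated on the $\sqrt{n}\,\mathrm{dip}$ scale on which the null
distribution is asymptotically stable.  The alternative `KDE_PEAKS`
method counts local maxima of a Gaussian kernel density (Silverman
bandwidth, 512-point grid), ignoring minor peaks below 10% of the major
peak's height; it matches the visual "one peak or two" reading of a
histogram.  Classes smaller than `min_n` are never split: the dip test
has little power there and a spurious split would invent an MMS
stratum.  `min_n` defaults to 50 at site level; the region-level
default is 10, because region sets are small by nature (each
observation already summarizes a whole region) and a guard of 50 would
simply disable the second layer for realistic region counts.

## From sites to regions

Array probes are too sparse to call regions directly; the segmentation
follows four steps:

1. **Build.** Adjacent CpGs on a chromosome join one candidate region
   iff their gap is at most the applicable threshold *and* they carry
   the same final site-state.  The threshold is 300 bp when both probes
   are island-associated (inside a CpG island or within 300 bp of one)
   and platform-specific otherwise: 11,300 bp on HM450K, 4,800 bp on
   EPIC, reflecting each platform's inter-probe gap distribution.  A
   mixed island/open-sea pair uses the permissive open-sea gap so island
   shores are not split.
2. **Filter.** Regions with fewer than 3 CpGs cannot support a regional
   state and are dropped (their members are remembered).
3. **Re-merge.** Dropping a one- or two-CpG state flicker can cut one
   domain into two.  Surviving neighbours re-merge when their boundary
   gap passes the same threshold *and* the boundary is of the healing
   kind: dropped CpGs lie between them (merged regardless of flank
   states, absorbing the dropped CpGs), or the flanks carry the same
   state.  A plain state-change boundary is left alone — by
   construction its gap always passes the threshold, so merging on gap
   alone would undo every state split and collapse each chromosome into
   one region.  The step iterates to a fixpoint;
   `remerge_same_state_only` restores the stricter behaviour.
4. **Classify.** Region mean beta-values (unweighted over member CpGs),
   chained per chromosome, go through the same two-layer procedure,
   yielding UMR/MMR/FMR.  With fewer than `min_regions` (10) regions an
   HMM fit is not meaningful and fixed thresholds (UMR < 0.25,
   FMR > 0.75) are used, with a prominent warning.

Region spans run from the first to the last member CpG; nothing is
claimed about unprobed flanking sequence.  Coordinates are 1-based
inclusive internally (Illumina manifest convention) and convert to
0-based half-open BED at the file boundary.

## The synthetic methylome

`simulate_methylome()` generates the structure the model assumes, with
known truth: alternating open-sea stretches (probe spacing 500-4,000
bp) and CpG islands (500-2,000 bp long, spacing 20-100 bp); a planted
three-state Markov chain along each chromosome (sticky diagonal 0.98,
so state runs span tens of CpGs, as methylation domains do); and
per-state beta noise at means 0.05/0.5/0.95 with sd 0.05, drawn from
the state's truncated normal by inverse-cdf sampling.  Sampling the
truncated distribution rather than clipping normal draws matters: with
mean 0.95 and sd 0.05 about 16% of normal draws land beyond 1, and
clipping them would pile an atom onto the boundary that real
beta-values do not show — the bimodality gate then (correctly) reports
that atom as a second mode and the full-methylated class gets split in
two.  Three strata are planted — not two — so the
MMS/MMR pathway is exercised; a two-state setting falls out by giving
one stratum zero stationary mass.  The chain is initialized from the
stationary distribution of its transition matrix and restarted on each
chromosome.

What the simulator does *not* emulate: probe chemistry and
normalization artifacts (type-I/II probe differences), detection-
p-value structure (a constant stands in), SNP-overlapping probes, and
any coupling between island position and methylation state.  Passing
the recovery tests therefore shows the inference machinery is correct
under the model's own assumptions — it does not certify performance on
real arrays, where preprocessing choices dominate.

## Numerical choices and degenerate inputs

* All HMM arithmetic is in log space with pairwise log-sum-exp; no
  scaling-factor variant exists.
* Viterbi ties break towards LOW, making decoding deterministic; ties
  have measure zero on continuous data.
* Transition pseudocount 0.5 guards empty states on small inputs.
* Baum-Welch stops when the log-likelihood improves by less than `tol`
  (1e-4) or after `max_iter` (100) iterations; `max_iter = 0` returns
  the initialization untouched.
* A profile whose initialization puts every site in one class skips the
  HMM (no two-state model can be initialized) and labels the class by
  its unimodal fallback.
* Duplicate (chrom, pos) records are dropped with a warning; rows with
  missing beta are dropped, not imputed.
* The test-size choices (e.g. 3,000-CpG synthetic methylomes, 5,000-site
  recovery chains, 200 Viterbi oracle instances) keep the default suite
  in the minutes range while leaving the measured tolerances far from
  their failure points.

## Known limitations

* Exactly two states per layer; covariate-dependent transitions and
  beta-distribution emissions are out of scope.
* The CpG-island track and any SNP blacklist are user-supplied inputs;
  none are bundled.
* Between-sample comparisons (differential methylation) are a different
  problem and are not addressed.
* On real data the method's output quality is bounded by upstream
  preprocessing (normalization, probe filtering), which this package
  deliberately does not perform beyond detection-p/sex/blacklist
  filters.
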