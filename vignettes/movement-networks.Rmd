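---
title: "From RFID reader logs to demes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RFID reader logs to demes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(demeflow)
```

demeflow turns longitudinal RFID detections from nest-box enclosures into
time-layered social networks, finds persistent social modules in them by
map-equation compression, and asks which of those modules behave as demes
— basic reproductive units — by linking them to a pedigree. This vignette
explains the models and the judgement calls; the README shows the
end-to-end worked example.

## From antenna reads to visits

Each nest-box entrance carries an outer and an inner antenna. A credible
entry is the signature outer → inner (we date the entry at the inner
read, the moment the crossing completes) and a credible exit is
inner → outer (dated at the outer read). An entry is paired with the next
exit from the same box by the same individual. Two conventions had to be
fixed where the signal alone is ambiguous:

* any *new* credible entry closes a still-open visit at the new entry's
  inner-read time — the animal must have slipped out undetected;
* every other pattern (repeated same-antenna reads, exits without entries,
  trailing reads) is *equivocal*: dropped and counted, never an error,
  because dirty reads are a fact of RFID data, not of the caller's code.

Which convention dates entries and exits is immaterial for the analysis:
any consistent choice shifts all pairwise overlaps by the same lags.

Records made during an enclosure check, and from the check until the
following midnight, are censored before anything else happens; visits that
straddle a censored window are clipped at its boundary, so no retained
visit time overlaps a check.

## Time layers

The censored record is cut into layers that act as network snapshots:
split at every enclosure-wide silent gap longer than 1 h, cut fragments
longer than 48 h into 48-h pieces, then iteratively merge any layer whose
first-to-last-read span is under 24 h into its nearest neighbour (the one
across the smaller gap; ties go to the earlier side). Merged layers may
legitimately exceed 48 h; spans settle in the 24–107 h range with most
under 72 h. "Gap" means silence of the whole enclosure, not of one
individual, because a layer is a population snapshot. A visit spanning a
layer boundary is split and its time apportioned to both layers, which
preserves total co-occupancy time.

## The per-layer network and the map equation

Within a layer, the edge weight between two individuals is the total time
they spent together in any nest box, irrespective of who else was present
(a triple co-stay feeds all three pairs). Individuals with visits but no
contacts stay in the layer as isolated vertices; individuals who never
entered a box are absent from that layer.

Structure is scored by the two-level map equation. A random walk on the
network is encoded with module codebooks; the average per-step codeword
length is

$$L = q_\curvearrowright H(Q) + \sum_m p_m^{\circlearrowright} H(P_m),$$

where $q_\curvearrowright$ is the total module-exit flow, $H(Q)$ the
entropy of relative exit flows, and each module codebook $P_m$ holds the
module's exit flow together with the visit rates of its members. For the
one-module partition $L$ is exactly the entropy of the visit rates, which
anchors the modularity

$$M = L_{\text{before}} / L_{\text{after}},$$

the compression rate achieved by the partition: 1 when nothing
compresses, larger the tighter and more exclusive the modules. $M$ is
independent of network size, unlike raw $L$.

Visit rates come from the stationary distribution of the row-normalised
walk with a uniform teleportation rate $\tau = 0.01$, which guarantees
ergodicity while distorting flows minimally; nodes without out-links
teleport with probability one. $\tau$ is exposed everywhere and tests of
closed-form cases set it to zero. The solver is a lazy-walk power
iteration (averaging each step with the previous distribution), which has
the same fixed point but converges on bipartite-ish toy graphs where the
plain iteration cycles.

$L$ is minimised by a Louvain scheme: greedy local moves in an order
shuffled by the seed, then aggregation of modules into super-nodes,
repeated until no move gains more than $10^{-10}$ bits (at most 100
passes). Ties among equally good moves go to the first candidate in the
shuffled order. The search is unconstrained — modules may have any size
and composition. If the best partition found fails to compress below the
one-module codelength the one-module solution is returned, so a reported
$M$ is never below 1. On every fixture small enough to enumerate
exhaustively (up to 8 state nodes) the optimiser attains the global
minimum; this is asserted in the tests rather than assumed.

## The time dimension: multilayer coupling and the relax rate

Each individual present in a layer becomes a state node. Intra-layer
links carry weight $(1-r)\,w_{ij}^{l}$. Cross-layer links connect
$(i,l)$ to $i$'s neighbours $j$ in every other layer $l'$ with weight

$$r \; \rho_i(l,l') \; \hat w_{ij}^{l'} \; s_i^{l},$$

where $\hat w^{l'}$ are $i$'s neighbour weights in $l'$ normalised to sum
one, $s_i^l$ is $i$'s strength in $l$, and
$\rho_i(l,l') = \sigma_i(l,l') / \sum_{l'' \neq l} \sigma_i(l,l'')$ with
the overlap similarity
$\sigma_i(l,l') = \sum_j \min(\hat w_{ij}^{l}, \hat w_{ij}^{l'})$.
Cross-layer flow is therefore strong exactly when an individual keeps the
same neighbours with similar relative weights, and the relax rate $r$
balances within-layer against cross-layer flow: $r = 0$ clusters layers
independently, $r = 1$ ignores layer boundaries. The overlap coefficient
is one concrete rendering of "similarity of neighbourhood patterns"; it
lives behind a single function so an alternative (cosine similarity, say)
could be swapped without touching the optimiser. The map equation is kept
two-level (flat modules); module labels are assigned in order of first
appearance and survive aggregation, which is what makes the
module-per-layer raster plots readable.

One modelling detail is decisive in the multilayer setting: module
codebooks assign codewords to *physical individuals*, not to state nodes.
Within a module, the state nodes of one individual across layers share a
codeword and their visit rates sum. Were each (individual, layer) state
node to pay for its own codeword, a module spanning $T$ layers would
carry a codebook $T$ times larger, and on records beyond a handful of
layers the objective would provably prefer shattering every layer into
its own modules — the opposite of the persistence the multilayer
construction exists to detect. With physical-node coding a persistent
module pays for its members once, and persistence wins exactly when the
same individuals keep interacting. The one-module reference
$L_{\text{before}}$ is, correspondingly, the entropy of the individuals'
total visit rates.

The consensual relax rate is chosen, not assumed: each experiment is
clustered at 21 rates equally spaced on [0, 1], solutions are compared
pairwise by normalized mutual information (Strehl–Ghosh normalisation,
$I/\sqrt{H_A H_B}$, over state nodes), each rate is scored by its mean
NMI against the other rates, and the chosen rate maximises the median
across experiments of those means (ties to the smaller rate). NMI is
defined as 1 when both partitions are single-module and 0 when exactly
one is.

## Robustness: the visit-reordering bootstrap

To ask whether an observed $M$ reflects synchronised association rather
than mere box preference, each individual's ordered visit start times are
held fixed while the (box, duration) payloads are permuted among those
slots. Every individual then spends exactly the same total time in the
same boxes — conserved bit-for-bit on integer seconds — but pairwise
synchrony is disturbed: associations carried by many repeated encounters
largely survive, one-off long overlaps die. The reported statistic is
the observed $M$ against the min/max (and 2.5/97.5% quantiles) of
bootstrap $M$ across replicates and rates. The permutation keeps start
times rather than, say, permuting inter-visit gaps, because the
fixed-slot scheme satisfies the conservation property exactly; the
gap-permutation alternative would not conserve layer placement.

## Space, sexes, and summaries

After partitioning, box possession in a layer is each module's share of a
box's total occupancy time (solitary time included); a box's exclusivity
is the largest share, and the layer's spatial-separation index is the
usage-weighted mean exclusivity over occupied boxes. Module
distinctiveness is the mean over interacting individuals of the fraction
of their interaction time spent with own-module members — the unweighted
per-individual mean, matching "mean proportion of time spent by
individuals"; a time-pooled variant is emitted alongside. Sex-specific
modularity re-evaluates $L$ on female–female, male–male or female–male
edges among adults (50 days and older at the layer mid-time) under the
*fixed* partition; with the identity filter it reproduces the full-data
value exactly. Period-summary networks average interaction strengths over
ten-layer windows with absent layers contributing zero, and vertices
carry their modal module over the window (ties to the earlier label).

## Pedigree links

Conception is dated 20 days before delivery. Multiple paternity is the
mean over qualifying litters (two or more offspring, all fathers
assigned) of the probability that two offspring drawn without replacement
have different fathers. Family-bond persistence is the within-module
fraction of parent–offspring arrows per layer, with mother–daughter and
father–son variants. Deme support takes the module the mother occupied in
the conception layer as the candidate, and scores the litter by the
fraction of gestation-window layers (mid-time between conception and
delivery) in which *both* parents sit in the candidate module. Window
layers where a parent has no assignment count against the support — the
denominator is the full window, since gestation covers those layers
whether or not the parents were observed; the observed-layers-only
variant is emitted as a secondary column. Supports sum per module into an
effective number of parental pairs; only modules with positive support
are called demes. The hard per-layer assignment stands in for "associated
preferentially": the clustering has already resolved preference.

## What the simulator emulates — and what it does not

The generator mimics the data-producing setting rather than any
particular dataset: a six-box enclosure, twelve adult founders (six per
sex, about 90 days old), planted modules that partition the boxes as
evenly as possible, 20-day gestation, litters of 3–7, transponders at 14
days, adulthood at 50 days, paternity skewed to a module's dominant male,
occasional permanent emigration, and minor/major checks (3-day and 36-day
cadence). Movement is driven by module-level communal rest bouts
(exponential bout and gap durations, means 40 and 30 min) that members
join with probability 0.9 and small entry/exit jitter; a joining member
targets the bout's box unless the mixing rate sends it to a uniform other
box. Communal bouts matter: they plant both the spatial preference and
the temporal synchrony that real co-nesting records carry, and synchrony
is precisely what the bootstrap destroys — a generator with independent
per-individual movement would make observed and bootstrap data
statistically identical and the bootstrap contrast meaningless.

Demography runs in continuous time with exponential waiting times —
simplicity over realism. The simulator does not attempt dominance
dynamics, circadian rhythm, antenna collisions, the exit-box
subpopulation, or inter-enclosure tubes (migration detection is tested on
hand fixtures). Passing tests on simulated data therefore demonstrate
correct recovery of planted block-plus-synchrony structure at realistic
read volumes; they do not certify behaviour on phenomena the generator
omits.

Test and acceptance runs use deliberately small problem sizes — 8–15 day
runs, 12 founders, 20 seeds — chosen so the planted structure is still
unambiguous (recovery NMI is essentially 1 at mixing 0.05) while a full
suite completes in minutes.

## Numerical choices and degenerate inputs

* Convergence: $10^{-10}$ bits for the optimiser, $10^{-14}$ L1 for the
  flow solver; both well below any reported difference.
* Zero-flow guards: all-zero networks error ("no links"); empty layers
  are dropped from the multilayer build; `NA` markers (never silent
  zeros) stand for undefined distinctiveness, separation, paternity, or
  persistence.
* Floating point: module exit flows can round to tiny negatives; the
  $p \log p$ helper treats anything non-positive as zero.
* Seeds: every stochastic routine takes an explicit integer seed; a
  fixed seed reproduces a simulation byte for byte and a fit exactly.

## Known limitations

The Louvain scheme is greedy; on adversarial networks it can in principle
stop short of the global optimum (the exhaustive-enumeration guarantee is
only asserted up to 8 state nodes). The cross-layer coupling couples all
layer pairs, which costs quadratic work in the number of layers an
individual spans; for records much longer than the study's this would be
the first thing to restrict to a layer horizon. The bootstrap conserves
start-time structure exactly and is accordingly conservative when visit
schedules themselves carry association information.
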