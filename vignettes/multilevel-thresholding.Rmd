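---
title: "Multilevel thresholding by reptile search with a global-best operator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel thresholding by reptile search with a global-best operator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsathresh)
```

## The problem

Multilevel thresholding partitions the gray levels of an image into $m$
classes using $m-1$ threshold values $t_1 < \dots < t_{m-1}$, each in
$[1, L-1]$ with $L = 256$ for 8-bit images. A level $p$ belongs to class $i$
iff $t_i \le p < t_{i+1}$ (with $t_0 = 0$, $t_m = L$; half-open intervals, so
the last class ends at $L-1$). The quality of a threshold vector is judged
from the normalized histogram $p_i = f_i / N$ alone, which is what makes the
problem tractable: the image enters only through 256 numbers.

Two classical objectives are supported, both maximized:

* **Otsu between-class variance**
  $\sigma_B = \sum_i \omega_i (\mu_i - \mu_T)^2$, where
  $\omega_i = \sum_{j \in C_i} p_j$, $\mu_i = \sum_{j \in C_i} j\,p_j /
  \omega_i$ and $\mu_T$ is the global mean.
* **Kapur entropy**
  $\sum_i H_i$ with
  $H_i = -\sum_{j \in C_i} (p_j/\omega_i) \ln (p_j/\omega_i)$.

Empty classes ($\omega_i = 0$) contribute zero to either objective rather
than raising an error: this keeps the search space smooth, and candidates
that waste a class are simply unrewarded. Kapur entropy uses the natural
logarithm; the base only rescales scores, never the arg-max. Color images are
thresholded per channel (R, G, B independently) — no joint 3-D histogram is
built.

For $k \le 3$ thresholds at 256 levels the optimum can be found exactly:
both objectives are additive over contiguous level segments, so
`exhaustive_search()` precomputes the score of every segment $[a, b)$ once
($\approx 33{,}000$ entries) and enumerates all
$\binom{255}{k}$ tuples as sums of $k+1$ table lookups (about 2.7 million
tuples for $k = 3$, a fraction of a second). Ties are broken by the
lexicographically smallest tuple so that results are deterministic. This
enumeration is the package's verification oracle: every claim made about the
stochastic optimizer is checked against it.

## The search algorithm

`rsa_optimize()` implements a reptile search algorithm (RSA), a
population-based metaheuristic whose four update strategies are assigned to
quarters of the iteration schedule $t = 1..T$:

| phase | window | update (coordinate $j$) |
|---|---|---|
| high walking | $t \le T/4$ | $best_j\,\eta_{ij}\,\beta - R_{ij}\,\mathrm{rand}$ |
| belly walking | $T/4 < t \le T/2$ | $best_j\,x_{r_1 j}\,ES(t)\,\mathrm{rand}$ |
| hunting coordination | $T/2 < t \le 3T/4$ | $best_j\,P_{ij}\,\mathrm{rand}$ |
| hunting cooperation | $3T/4 < t \le T$ | $best_j - \eta_{ij}\,\epsilon - R_{ij}\,\mathrm{rand}$ |

with the auxiliary quantities

* $P_{ij} = \alpha + (x_{ij} - \bar{x}_i) / (best_j (UB - LB) + \epsilon)$
  (percentage difference from the best),
* $\eta_{ij} = best_j P_{ij}$ (hunting operator),
* $R_{ij} = (best_j - x_{r_2 j}) / (best_j + \epsilon)$ (reduction function),
* $ES(t) = 2 r_3 (1 - t/T)$, $r_3 \sim U[-1, 1]$ drawn once per iteration
  (evolutionary sense, shrinking from magnitude 2 toward 0).

Every `rand` is a fresh uniform $[0,1]$ draw per coordinate from one seeded
generator; $r_1$ is a uniform candidate index per candidate move and $r_2$ is
resampled per coordinate. The first two phases explore (the new position is
built mostly from the best solution and a random peer, so steps are large),
the last two exploit (positions contract toward the incumbent best).

### The global-best operator

After each candidate's RSA move, a particle-swarm velocity refinement is
applied from its current position:
$$v' = w\,v + c_1\,\mathrm{rand}_1 (Pbest_i - x_i) + c_2\,\mathrm{rand}_2
(Gbest - x_i), \qquad x' = x_i + v',$$
with the inertia $w$ decaying linearly from `w_max` to `w_min` over the run.
The wiring of this operator into the phase structure is a genuine design
choice — the operator's equations do not by themselves say whether it
replaces a phase or augments all of them. This package applies it as a
per-candidate refinement after every RSA phase move, with greedy acceptance:
the best of {old position, RSA move, Gbest move} is kept, and personal bests
and the global best are updated after every evaluation. Augmentation
preserves the four-phase exploration/exploitation structure while the
operator steadily pulls the population toward the incumbent best; greedy
acceptance additionally guarantees a monotone best-so-far trace (elitism),
which the convergence analysis of such optimizers presumes. The cost is two
objective evaluations per candidate per iteration instead of one.

### Decoding and fitness

The search runs in a continuous box $[1, L-1]^k$. Fitness is always
evaluated on decoded integer thresholds: clamp to $[1, L-1]$, round half-up,
sort, and resolve duplicates by moving the later value to the next free
level above (wrapping downward when the top of the range is full). Evaluating
on the decoded integers (rather than on the continuous position) means the
reported optimum is exactly the score of the returned threshold vector — no
post-hoc rounding gap.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `population` | 25 | candidate solutions |
| `iterations` | 100 | iteration count $T$ (each phase gets $T/4$) |
| `runs` | 30 | repetitions in the benchmark harness |
| `beta` | 0.1 | high-walk exploration accuracy |
| `alpha` | 0.1 | hunting-cooperation accuracy |
| `epsilon` | 1e-10 | stabilizer in $R_{ij}$, $P_{ij}$ and the cooperation step |
| `w_max`, `w_min` | 0.9, 0.2 | inertia decay range of the Gbest operator |
| `c1`, `c2` | 2, 2 | acceleration coefficients |

The population/iteration/run defaults and $\beta = \alpha = 0.1$ are the
standard study conditions for this family of segmentation benchmarks; the
Gbest operator borrows the conventional PSO settings. $\epsilon$ has no
conventional published value; $10^{-10}$ is small enough to be inert in
every expression it stabilizes while preventing division by zero when a
best-coordinate is 0.

## Quality metrics

A threshold vector is turned into a segmented image by labeling pixels with
the class rule and replacing each pixel by its class's mean intensity
(rounded; empty classes fall back to the class-interval midpoint). Class
means minimize reconstruction RMSE, and give the identity
$\mathrm{RMSE}^2 = \text{total variance} - \sigma_B$ (exact before rounding),
which links segmentation quality directly to the Otsu objective and makes
PSNR non-decreasing in $k$ at the exhaustive optimum — a property the test
suite checks.

* $\mathrm{RMSE} = \sqrt{\frac{1}{MQ}\sum (I - Seg)^2}$
* $\mathrm{PSNR} = 20 \log_{10}(255 / \mathrm{RMSE})$ dB, with an `Inf`
  sentinel for a perfect match
* $\mathrm{SSIM} = \frac{(2\mu_I\mu_{Seg} + C_1)(2\sigma_{I,Seg} + C_2)}
  {(\mu_I^2 + \mu_{Seg}^2 + C_1)(\sigma_I^2 + \sigma_{Seg}^2 + C_2)}$ with
  $C_1 = 6.5025$, $C_2 = 58.52252$

SSIM is computed globally in a single window from the formula above, not
with the 11×11 Gaussian sliding window of the original SSIM construction:
the global form with these fixed constants is the variant this benchmark
family reports. Variances use population normalization ($MQ$, no $n-1$).
Color images are scored per channel and averaged.

## Benchmark harness and ranking

`benchmark_optimizers()` races any set of optimizers obeying the contract
`(histogram, k, objective, config, seed) -> list(thresholds, fitness)` over
images × threshold counts × repeated runs, with deterministic per-run seeds.
`aggregate_runs()` reports the mean and sample (n−1) standard deviation per
cell. `rank_benchmark()` performs the Friedman analysis: each image × K cell
is a case, algorithms are ranked within cases (rank 1 best, ties receiving
average ranks — the standard Friedman treatment), and rank sums, mean ranks,
final ordinal ranks and the statistic
$\chi^2 = \frac{12n}{A(A+1)} \sum_j (\bar R_j - \frac{A+1}{2})^2$ are
reported with a $\chi^2_{A-1}$ p-value. No multiple-testing correction is
applied; the statistic is informative, not confirmatory. Because only ranks
enter, the analysis is invariant under any monotone transformation of the
scores. A deliberately naive random-search baseline
(`optimizer_random_search()`) ships with the package so the harness always
has a second contender.

## Synthetic fixtures

The package is fully testable without external images:

* `gaussian_mixture_image()` — pixels sampled from a Gaussian mixture,
  rounded and clipped to $[0, 255]$. Two to seven well-separated modes cover
  the interesting $k$ range: a $k$-threshold search on a ($k{+}1$)-mode
  histogram has a known coarse structure (one threshold per valley), so the
  exhaustive oracle provides a ground truth to recover.
* `delta_histogram()` — all mass on a few levels; closed-form optima.
* `ramp_image()` — an exactly uniform histogram, where Kapur's $k = 1$
  optimum is analytically $t = 128$ with score $2\ln 128$.

These fixtures emulate the *statistical* structure the method assumes —
multimodal intensity histograms — and nothing else. Passing tests therefore
demonstrate correctness of the objectives, the search dynamics, the metrics
and the ranking machinery; they do not demonstrate segmentation quality on
natural photographs or radiographs, which have textured, spatially
correlated histograms that no pixel-independent mixture reproduces.

## Numerical choices and degenerate inputs

* Tie-breaks: exhaustive enumeration keeps the lexicographically smallest
  maximizer (strict-improvement scan in lexicographic order); ordinal final
  ranks share the better ordinal on ties.
* A histogram with all mass at one level scores 0 under both objectives for
  every threshold vector; the optimizer still returns a valid vector.
* Thresholds are restricted to $[1, L-1]$ so no class is structurally forced
  empty at the low end.
* `exhaustive_search()` refuses enumerations beyond ~3.5 million tuples
  (capacity error) rather than silently running for hours.
* All randomness flows from one seed; identical (inputs, config, seed) give
  bit-identical results, including written output files.

## Problem sizes in the test suite

The tests exercise full study-condition runs (population 25, 100 iterations)
for the oracle-recovery and elitism properties — 100 and 20 runs
respectively on 64×64 and 48×48 mixture images — and scale the remaining
property checks down to small populations (6–15) and short schedules (8–40
iterations) on 24×24 to 64×64 fixtures, which is ample to exercise every
code path while keeping the default suite fast.

## Known limitations

* No 2-D (spatial) histogram objectives; the method is histogram-only, so
  spatial coherence of the segmentation is never optimized.
* SSIM is the global single-window form; it is not comparable to sliding
  window SSIM values from other software.
* The comparison metaheuristics of the wider literature (marine predators,
  salp swarm, whale, Aquila, dynamic PSO) are not re-implemented; the
  harness accepts any optimizer through the pluggable contract instead.
* JPEG input is read-only, and 16-bit inputs are rescaled to 8-bit on load;
  there is no native 16-bit pipeline.
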