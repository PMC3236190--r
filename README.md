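# loglogstep

Detection of short repeating patterns in event-interval time series —
typically interspike-interval (ISI) sequences from neural recordings —
under heavy jitter and noise, via staircase structure in the log-log plot
of the correlation integral.

## The idea

Embed the interval series $x_1, x_2, \dots$ in $m$ dimensions with the
coordinate-delay construction
$\mathbf{y}_i = (x_i, \dots, x_{i+m-1})$ and estimate the correlation
integral

$$C(\varepsilon) = \Pr\left(\lVert \mathbf{y}_i - \mathbf{y}_j
\rVert_\infty \le \varepsilon\right),$$

the fraction of embedded point pairs within maximum-norm distance
$\varepsilon$. A noise-free pattern of length $p$ collapses the embedded
points onto $p$ cyclic-shift clusters, so $\log C(\varepsilon)$ versus
$\log \varepsilon$ is a staircase with one step per distinct
inter-cluster distance — and the number of observable steps is bounded in
closed form as a function of $p$ and $m$ (for odd $p$:
$N_{\min} = \tfrac{p-1}{2}\lceil p/\tilde m\rceil$,
$N_{\max} = \tfrac{p-1}{2}(p-\tilde m+1)$ with
$\tilde m = \min(m, p)$; analogous forms for even $p$). Because cluster
mass sits at discrete distances while noise mass spreads over a
continuum, the staircase remains detectable far into the noise-dominated
regime. The package provides:

- `generate_series()` / `make_surrogate()` — patterned ISI simulator with
  jitter, two noise-insertion paradigms (event-wise, pattern-wise with
  the rescaled insertion probability $\tilde q = (1-q)/(1-q+qp)$), and
  permutation surrogates;
- `embed_series()`, `correlation_integral()` — delay embedding and a fast
  (C++) maximum-norm correlation integral on a logarithmic radius grid;
- `curve_derivative()`, `count_peaks()`, `criterion_a()`,
  `criterion_b()`, `criterion_c()` — step/plateau detection and the three
  weighted visibility criteria (single step at $m=p$ with surrogate
  comparison; exactly $p$ peaks at $m=1$; plateau-flatness difference
  between $m=p$ and $m=p-1$);
- `step_bounds()`, `brute_force_step_count()`, `decompose_shift_graph()`,
  `bounds_table()` — the noiseless step-count bounds and their
  brute-force oracle;
- `phase_sweep()`, `classify_regions()` — jitter-by-noise phase diagrams
  with excellent/fair/ambiguous region labels;
- `run_guideline()` — a screening work-flow proposing candidate pattern
  lengths for unlabelled data.

## Worked example

A period-three pattern (intervals 1, 3, 4), contaminated with 5% jitter
and 80% pattern-wise noise — conditions under which spectral methods are
hopeless:

```r
library(loglogstep)

s  <- generate_series(c(1, 3, 4), jitter = jitter_spec(0.05),
                      noise = noise_spec(0.8), n_events = 10000, seed = 42)
qs <- quality_scores(s, p = 3, n_ref = 250, n_surrogates = 5, seed = 44)

su  <- make_surrogate(s, seed = 46)
qsu <- quality_scores(su, p = 3, n_ref = 250, n_surrogates = 5, seed = 47)

cat("series:    q_a =", qs$q_a,  " q_b =", qs$q_b,  " q_c =", round(qs$q_c, 3),  "\n")
cat("surrogate: q_a =", qsu$q_a, " q_b =", qsu$q_b, " q_c =", round(qsu$q_c, 3), "\n")
```

```
series:    q_a = 6  q_b = 2  q_c = 1.667
surrogate: q_a = 0  q_b = 0  q_c = -0.167
```

At 80% noise the series still attains the full single-step score at
$m = 3$ (`q_a = 6`, the sum of the ladder weights 1+2+3), detects the
three steps at $m = 1$ at the middle sharpness level (`q_b = 2`), and
shows a positive plateau-flatness gain of $m=3$ over $m=2$ (`q_c = 1.667`
flat samples, weighted) — while its permutation surrogate scores zero or
negative on all three. Screening the milder 10%-noise version of the same
series without assuming the pattern length:

```r
s10 <- generate_series(c(1, 3, 4), jitter = jitter_spec(0.1),
                       noise = noise_spec(0.1), n_events = 10000, seed = 42)
run_guideline(s10, p_max = 5, n_ref = 250, seed = 45)
```

```
Pattern-length screening report
  plateau-flatness gain by dimension pair (m vs m-1):
 p     c_diff surrogate_max exceeds
 2  1.1666667    -4.0000000    TRUE
 3  0.3333333    -1.1666667    TRUE
 4 -3.8333333     0.3333333   FALSE
 5  0.6666667    -0.1666667    TRUE
  candidate pattern length: 3
  confirmation at p = 3: criterion (a) = 3.000, criterion (b) = 3.000
```

The flatness gain beats the surrogate ensemble contiguously up to
$m = 3$ and not at $m = 4$, identifying a length-3 pattern; the noiseless
bounds table (`bounds_table(2:5, 1:5)`) predicts the matching step counts
(3 steps at $m=1$, 1 at $m=3$ for $p=3$).

A thin command-line front end with subcommands `simulate`, `curve`,
`criteria`, `bounds`, `phase` and `guideline` is installed at
`inst/cli/loglogstep.R`.

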