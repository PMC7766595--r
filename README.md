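# chromdiv

Quantifying the **diversity of chromatin compartments** in DNA-stained
cancer cell nuclei, and turning it into a prognostic patient-level marker.

## The problem and who this is for

In Feulgen-stained nuclei the measured optical density (OD) is proportional
to local DNA content, so images of tumour cell nuclei show interleaved
regions of relatively highly condensed (heterochromatin-like, *dark*) and
relatively weakly condensed (euchromatin-like, *bright*) chromatin.
Changes in the number and size of such chromatin compartments accompany
carcinogenesis, and nuclei whose compartments are more *diverse* — many
compartments with widely varying sizes and DNA densities — indicate poorer
prognosis. `chromdiv` is aimed at researchers in quantitative
pathology / nuclear image cytometry who want a fully automatic,
reproducible implementation of this marker together with the evaluation
machinery (balanced accuracy, Kaplan–Meier, log-rank, Cox) and a synthetic
data generator, since the original clinical cohorts are access-restricted.

## The method

For each nucleus image (OD values on a 10-bit scale with a binary nuclear
mask):

1. **Segmentation.** Every nuclear pixel is labelled by a two-sided
   generalisation of Niblack's adaptive threshold: with local mean
   $\mu(x)$ and local standard deviation $\sigma(x)$ over the in-mask
   pixels of a $(2r{+}1)\times(2r{+}1)$ window,

   $$\text{label}(x)=\begin{cases}
     \text{dark} & \text{OD}(x) > \mu(x) + k\max(\sigma(x),\sigma_{\min})\\
     \text{bright} & \text{OD}(x) < \mu(x) - k\max(\sigma(x),\sigma_{\min})\\
     \text{grey} & \text{otherwise.}
   \end{cases}$$

   Candidate 8-connected dark/bright regions are validated in the spirit of
   Yanowitz–Bruckstein: a region survives only if it has at least
   `min_region_size` pixels and the mean Sobel gradient magnitude along its
   boundary is at least `g_min`.
2. **Entropy sums.** Per nucleus and per compartment class, the Shannon
   entropy (bits) of the compartment-size histogram (log-spaced bins) plus
   the entropy of the within-compartment OD histogram (linear bins):
   $e = H(\text{size}) + H(\text{OD})$.
3. **DESH.** Per patient and class, the *dual entropy sum histogram*: the
   entropy sums of all the patient's nuclei, quantised with equal-frequency
   edges fitted on the pooled training nuclei ($Q = 40$ bins), normalised.
4. **Adaptive features.** Each DESH bin is weighted by its outcome
   contrast in the training set,
   $w_b = (\bar p_{\text{poor}}(b)-\bar p_{\text{good}}(b)) /
   (\bar p_{\text{poor}}(b)+\bar p_{\text{good}}(b)+\varepsilon)$, and the
   patient's feature is $F=\sum_b p_b w_b \in [-1,1]$ — one feature for
   dark, one for bright compartments.
5. **Classification.** An equal-prior Gaussian classifier with common
   (pooled) covariance draws a linear decision line in the
   $(F_{\text{dark}}, F_{\text{bright}})$ plane; patients on the
   poor-prognosis side are called **DCC** (diverse chromatin compartments),
   the others **SCC** (similar chromatin compartments).

The call can be integrated with a pathological risk classification
(HPR/LPR) into three risk groups: low = SCC∧LPR, high = DCC∧HPR, medium
otherwise.

## Worked example

```r
library(chromdiv)

# simulate a small cohort with planted class differences
cp <- cohort_sim_params("separated", n_train = 12, n_test = 12,
                        nuclei_per_patient = 12, seed = 42)
co <- generate_cohort(cp)

marker <- train_marker(co$train)          # segment -> entropy -> DESH -> fit
scored <- score_cohort(co$test, marker)   # held-out patients
confusion_metrics(scored$call, scored$outcome)[c("bccr", "sensitivity",
                                                 "specificity")]
#> $bccr        [1] 1
#> $sensitivity [1] 1
#> $specificity [1] 1

aggregate(cbind(feature_dark, feature_bright) ~ outcome, scored, mean)
#>   outcome feature_dark feature_bright
#> 1    good   -0.9384921     -0.9226190
#> 2    poor    0.9603175      0.8988095
```

The two adaptive features sit near −1 for good-outcome and near +1 for
poor-outcome patients, so the planted separation is recovered perfectly at
this effect size. Survival machinery operates on the same scored table:

```r
cox_fit(transform(scored, dcc = as.integer(call == "DCC")), "dcc")[, c("hr", "p")]
km_estimate(scored, scored$call, horizons = 10)$at_horizons
```

A shell entry point with `simulate` / `train` / `score` subcommands is
installed at `inst/scripts/chromdiv.R`.

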