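---
title: "Disambiguating the period in clinical German text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disambiguating the period in clinical German text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satzpunkt)
```

## The problem

In German clinical narratives the period character is severely overloaded.
It ends sentences, but it also mandatorily terminates abbreviations
("St.p.", "ca.", "Pat."), marks ordinals ("3." = "third"), appears inside
dates ("3.5.2014") and codes ("C43.5"), and — in telegram-style discharge
summaries — physicians constantly coin *ad-hoc* abbreviations by truncating
long compound words ("Tumordurchm." for "Tumordurchmesser"). A period can
even play a double role, closing an abbreviation *and* a sentence at once.
Getting this wrong breaks everything downstream: sentence splitting,
abbreviation expansion, information extraction.

`satzpunkt` frames the problem as two binary classification tasks over
*period sites*. A site is written `L• R`: a token `L•` ending in the
candidate period, followed by whitespace and the next token `R`. Task one
asks whether the period marks an abbreviation; task two asks whether it
delimits a sentence. Both are solved by linear support vector machines
over hand-engineered feature blocks, and the blocks can be toggled
individually to study what each contributes.

## Tokenization and normalization

Text is split on spaces, tabs and newlines, so periods always stay inside
tokens. Newline runs are recorded on the following token because line
breaks carry formatting information. Tokens consisting only of punctuation
(artifacts of record extraction) are merged into the preceding token in a
single left-to-right pass. A site is any token whose surface ends with a
period; token-internal periods (as in the agglutination "sek.knot.SSM" or
the code "C43.5") never create sites, and neither do periods directly
followed by a character — those are typing errors outside this package's
scope.

Two normalizations supply the classifier's view of a site.
`normalize_left()` keeps letters, digits and periods (collapsing adjacent
periods); internal periods are kept deliberately since they are strong
abbreviation evidence. `normalize_right()` keeps only letters and digits.
"Non-word character" means anything that is not a Unicode letter or digit,
so umlauts and ß survive.

## Collocation statistics and the scaling power set

The corpus-statistical backbone is Dunning's log-likelihood ratio. For a
word type $w$ (the normalized left token without its terminal period) the
2×2 table of counts $C(w,\bullet), C(w,\neg\bullet), C(\neg w,\bullet),
C(\neg w,\neg\bullet)$ yields

$$\log\lambda = -2\log\frac{L(H_0)}{L(H_A)},$$

where $H_0$ says the period occurs independently of the preceding word.
The statistic is computed in log space as the G statistic of the table
(observed-vs-expected form) with the $0\log 0 = 0$ convention; `log1p` of
the relative deviation keeps nearly independent tables accurate, and a
unit test cross-checks against a direct evaluation of the two binomial
likelihoods at $10^{-9}$ relative tolerance.

Raw $\log\lambda$ finds abbreviations with high recall but poor precision,
so six scaling functions re-weight it: S1 boosts period-collocated types
($e^{C(w,\bullet)/C(w,\neg\bullet)}$), S2 is a signed collocation ratio in
$[-1,1]$, S3 punishes long words ($e^{-\mathrm{len}}$), S4 rewards internal
periods, S5 exponentially penalizes period-free occurrences, and S6
*adds* the number of dictionary entries having each period-delimited
subword as a prefix — ad-hoc abbreviations are prefixes of real dictionary
words, and being additive S6 can pull a negatively scaled value back above
zero. Rather than fixing a decision threshold, *every* non-empty subset of
$\{S_1,\dots,S_6\}$ is applied as a sequential composition (ascending
index; the order only matters because S6 is additive) and each of the 63
results becomes a feature. The SVM's feature-relevance ranking then
reveals which combinations matter.

Word length counts non-period characters only (`word_length("St.p.")` is
3), so internal periods are not penalized. From all types with a
significant period collocation (G above the $\chi^2_1$ critical value at
$\alpha = 0.01$) that occur more often with a period than without, the
package estimates the mean $\mu$ and population standard deviation
$\sigma$ of abbreviation lengths and derives three right-tail borders
$b_1 = \mu + 1.645\sigma$, $b_2 = \mu + 1.960\sigma$,
$b_3 = \mu + 2.576\sigma$ used by the length features.

## Lexicons

Two word lists support the lexicon features. The medical-domain dictionary
(MDDict) is built from word sources by discarding every token ending in a
period and then removing every word that matches a known short form once
its terminal period is stripped — so a successful lookup argues against
the abbreviation reading. The closed-class dictionary (CCDict) lists
function words (prepositions, determiners, conjunctions, pronouns,
auxiliaries, modals): in German these are the only words not capitalized
by default, so a *capitalized* closed-class token right of the period is a
strong sentence-start signal. Prefix queries into MDDict (for S6) are
case-sensitive on the first character only, because truncations preserve
the initial capitalization of the word they shorten. The package ships
small synthetic lexicons; no external resources are harvested.

## Feature blocks

For abbreviation detection, in fixed order: three binary rules on the
normalized left token (internal period, contains digit, all characters
upper case — the acronym shape, which digit-bearing strings fail), the
four contingency counts plus $\log\lambda$, the 63 scaling features, the
MDDict lookup, eight length features (length, the three borders as
constants, three above-border flags, $\mu -$ length), and a one-hot
word-type block over masked types (digit runs collapsed to "d", so every
ordinal shares the type "d" and "C43.5" becomes "Cd.d").

For sentence detection: two language features (capitalized-closed-class
and MDDict membership of the right token), four rules (period in the raw
right token; digit, all-upper and capitalization on its normalized form),
a one-hot text-format block (no / single / double newline before the right
token — only a double newline is a reliable paragraph marker in
extraction-contaminated text), the eight length features computed on the
right token, one-hot word types for the right context (suffixed `_RC`) and
the left token, and finally the prediction of a trained abbreviation model
on the very same site: an abbreviation reading argues against a sentence
boundary, and this single feature is consistently the most relevant one.

Word-type vocabularies are frozen from the training split; unseen types at
prediction time yield all-zero blocks, so no information leaks from test
data. The closed-class feature's capitalization condition can be switched
to plain membership (`cc_capitalized = FALSE`); the capitalization-
conditioned variant is the default because membership alone fires on every
mid-sentence function word.

## Training protocol

Features are scaled per column onto $[-1, 1]$ with parameters estimated on
the training data only (test data is mapped with the same parameters and
may leave the range; constant columns map to 0), then each instance vector
is normalized to unit Euclidean length. The SVM uses a linear kernel; the
solver is libsvm via `e1071`, wrapped so that the explicit weight vector
$w$ and bias $b$ are recovered for the decision function
$f(x) = \mathrm{sign}(w^\top x + b)$ and for Guyon-style relevance ranking
by squared weight $w_j^2$ (ties broken lexicographically by feature name).

The soft-margin cost $C$ trades training error against margin. `select_c()`
scans a log grid over $[0.001, 1000]$ by stratified cross-validation,
maximizing micro-averaged F1 and preferring the smallest cost on ties
(stronger regularization). Model fitting defaults to $C = 1$, which is
adequate for the compact feature blocks; the stepwise evaluations select
$C$ per step over the coarse grid $\{0.01, 1, 100\}$ with 3-fold
cross-validation, because large sparse word-type blocks genuinely need a
harder margin — with $C$ fixed at 1 the unit-norm dilution of a
thousand-column one-hot block can transiently *lower* the curve, which
per-step selection removes.

Evaluation reports micro-averaged F1 (true positives, false positives and
false negatives pooled over both classes; for a single-label binary task
this equals accuracy, and a property test asserts that identity), with
macro-F1 alongside. `cross_validate()` performs stratified k-fold
cross-validation with per-fold preprocessing. Two rule baselines anchor
the comparisons: a site is a baseline abbreviation when the character
after the period is a lower-case letter, and a baseline sentence end when
the normalized right token is capitalized. `compare_classifiers()` tests
two classifiers' accuracies with a chi-squared test on the
classifier × correct/incorrect table (no continuity correction), with
McNemar's paired test as an alternative; degenerate tables are flagged
rather than tested. `cohens_kappa()` measures inter-annotator agreement;
`chernoff_sample_size()` reproduces the distribution-free bound
$n \ge \frac{2+\epsilon}{\epsilon^2}\ln\frac{2}{\delta}$ used to size a
gold standard (3024 snippets at $\epsilon = \delta = 0.05$; the fractional
part of the bound is truncated).

## The synthetic corpus

Real discharge summaries cannot be redistributed, so the package generates
labeled corpora that emulate their statistical structure: telegram
sentences over a synthetic German-like medical vocabulary built by stem
compounding (so ad-hoc truncations are genuine prefixes of dictionary
entries, as S6 requires), a weighted inventory of lexicalized clinical
abbreviations, ordinals, dates, acronyms, ICD-like codes, capitalized
sentence starts, double-role sentence-final abbreviations, paragraph
double-newlines and spurious single-newline contamination. Gold labels
are emitted at generation time, when each period's role is known by
construction — never re-derived by rules — so the generator and the site
extractor cannot share a bug silently.

Default rates (18% lexicalized abbreviations, 8% truncations, 5%
ordinals, 3% dates, 4% acronyms, 3% codes per internal token slot; 15%
double-role sentence ends; 30% paragraph breaks; 8% newline
contamination) keep the two label marginals roughly balanced, similar in
spirit to a corpus where periods are frequent and both readings common.
What the generator does *not* model: real German syntax and agreement,
spelling errors, omitted spaces after periods (explicitly out of scope),
and the heavy-tailed lexical repetition of genuine clinical prose. Passing
the recovery tests therefore bounds implementation defects — the synthetic
task is easier than real clinical text — and says nothing quantitative
about performance on real records.

The packaged evaluations use corpora of 1,250 sentences (about 3,000
period sites) for training and testing, matching the size a
Chernoff-bound gold standard would have, and the full suite trains each
classifier once plus one model per stepwise step. On these corpora the
all-feature abbreviation classifier reaches held-out micro-F1 above 0.99
against a baseline near 0.61, the sentence classifier above 0.93 against
a baseline near 0.71, and the abbreviation feature ranks first in the
sentence model — the same qualitative structure the method is designed to
exhibit.

## Numerical and degenerate-case choices

* S1's exponent uses a denominator floored at 1 (types never seen without
  a period) and is capped at 700 so `exp()` stays finite.
* S2 is defined as 0 for types with no occurrences at all.
* S5 floors word length at 1; an empty normalized token contributes a
  neutral factor.
* Ties in cost selection go to the smallest cost; ties in feature ranking
  break lexicographically; stratified fold assignment is seeded.
* Cohen's kappa is 1 when both raters are constant and identical, and 0
  when expected agreement is 0.
* All-zero contingency tables and unlabeled training sites raise errors
  instead of propagating NaN.
* The count table keys on normalized types; tokens whose normalization is
  empty (pure symbols) are not counted.

## Limitations

The package detects the role of periods followed by whitespace; it does
not correct omitted spaces, split agglutinations like "sek.knot.SSM", or
normalize abbreviations to their long forms. The synthetic generator's
uniform word draws understate the lexical burstiness of real text, which
flatters word-type features less than a real corpus would. Reported
numbers on synthetic corpora validate the implementation, not clinical
performance.
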