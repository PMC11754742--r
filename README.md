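# editpause

Junction profiling and pause-site detection for uridine insertion/deletion
(U-indel) RNA editing amplicons.

Kinetoplastid mitochondrial mRNAs (e.g. the pan-edited ATP synthase subunit
6 transcript of *Trypanosoma brucei*) are matured by guide-RNA-directed
insertion and deletion of U residues, proceeding generally 3'→5'.  When an
editing factor is knocked down, editing can stall at specific **editing
sites (ES)**.  `editpause` measures such stalls from amplicon deep
sequencing:

* builds an ES coordinate system from a pre-edited/fully-edited reference
  pair (the two share an identical non-T *backbone*; ES are the gaps
  between backbone residues, numbered from the 3' end);
* reduces every read to its per-ES U-count vector **u** by exact backbone
  matching, excluding reads with non-T SNPs or indels;
* classifies reads (pre-edited / partially edited / fully edited over the
  amplicon window) and calls per-read junction boundaries — the **JSS**
  (first ES, moving 3'→5', failing the canonical sequence, i.e. the
  smallest ES *i* with u<sub>i</sub> ≠ can<sub>i</sub>) and the **JES**
  (5'-most ES with any editing action, the largest ES *j* with
  u<sub>j</sub> ≠ pre<sub>j</sub>);
* normalizes each sample to 100,000 counts and detects **EJES**
  (exacerbated junction end sites — editing pause sites) between induced
  and uninduced conditions: mean fold change ≥ 3 and ≥ 100 normalized JES
  counts in ≥ 2 induced replicates, all thresholds configurable;
* computes windowed statistics (percent of reads with JES in an ES window,
  Student's t across replicates) and per-sequence pause tables;
* ships a synthetic read generator (progressive 3'→5' editing, junctions,
  planted pause sites, substitution errors) with per-read ground truth, so
  the whole pipeline is testable without external data.

## Worked example

```r
library(editpause)

s <- build_scaffold(
  pre_seq    = "GGCGAAGTAGATTCGTAGCTAAGG",
  edited_seq = "GGCGAAGTTTTAGTATTCTTTGAGCTAAGG",
  name       = "demo")
s
#> editing_scaffold 'demo': 19 backbone residues, 18 editing sites
#>   pre-edited U total: 5   canonical U total: 11   sites with editing action: 4

w <- restrict_to_amplicon(s, fwd = "GGCGAAG", rev = "GCTAAGG")
w
#> amplicon_window: ES6-ES12 (7 sites), primers 7nt/7nt

rd <- "GGCGAAGTAGTTTTTATTCTTTGAGCTAAGG"
a <- align_read(s, w, rd)
a$u_obs
#>  ES6  ES7  ES8  ES9 ES10 ES11 ES12
#>    0    0    3    2    5    0    1
classify_read(a, s, w)
#> [1] "PARTIALLY_EDITED"
call_junction(a, s, w)
#> $jss
#> [1] 10
#> $jes
#> [1] 10
```

The read matches the canonical sequence from the 3' end of the window
through ES9, carries a non-canonical 5-U insertion at ES10 (the junction),
and is pre-edited 5' of it: editing has progressed to ES10 and paused
there, so both junction boundaries fall on ES10.  Aggregating such calls
over samples (`normalize_sample()`) and comparing conditions
(`detect_ejes()`, `percent_jes_in_window()`, `compare_conditions()`,
`filter_window_sequences()`) turns per-read pauses into per-site pause
profiles; `run_pipeline()` does all of it from a reference FASTA and a
sample sheet, writing TSV/JSON outputs.

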