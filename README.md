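# gaitmatch

Identity matching from walking patterns, for people working with
pose-estimation output rather than raw video: given per-frame body-landmark
sequences of the same subjects recorded from several camera views — one
*reference* (gallery) and one *target* (probe) bout per subject and view —
`gaitmatch` decides who each probe is, view by view, and then lets the views
vote.

## Method

The pipeline operates on skeleton keypoints (MediaPipe's 33 landmarks,
OpenPose/AlphaPose COCO-18, or any source exporting a long CSV of
`frame,joint,x,y[,z]`):

1. **Joint angles.** For each of 10 angles (left/right elbow, hip, knee, and
   ankle against toe and heel), three landmarks form a triangle with
   Euclidean legs *a*, *b* (into the vertex) and *c* (across). The interior
   angle follows from the law of cosines,
   θ = arccos((a² + b² − c²) / 2ab), giving a T × 10 matrix of angle time
   series per sequence. Angles are invariant to translation, rotation and
   uniform scaling of the landmarks, so image coordinates are fine as-is.
   Body-part subsets: *whole* (all 10), *upper* (2 elbow angles), *lower*
   (the other 8). COCO-18 skeletons have no foot landmarks, so there the
   whole body has 6 angles and the lower body 4.
2. **Correlation signature.** Each sequence can instead be summarised as the
   J × J Spearman rank-correlation matrix between its angle columns
   (fractional tied-average ranks, then the Pearson correlation of the rank
   vectors). Because all joints move together during walking, this
   inter-joint dependence pattern is an individual signature — and it does
   not depend on where in the gait cycle the recording starts.
3. **Matching.** A probe is compared against every gallery entry *in the
   same view* with dependent multi-dimensional dynamic time warping (DTW):
   local cost = Euclidean norm across feature dimensions, symmetric
   match/insert/delete steps, no window. Angle features warp over time;
   a correlation matrix is fed to DTW as its J ordered rows. The matched
   identity is the argmin of DTW distance, ikD = argmin_i S_iD.
4. **Voting.** The per-view identities are aggregated by majority vote (the
   statistical mode; ties resolved by smallest summed distance). Accuracy is
   reported both per (probe, view) pair and per voted probe.

The real multi-view gait databases this kind of method is evaluated on are
access-restricted, so the package ships a seeded synthetic cohort generator
(`sample_cohort()`, `simulate_gait_data()`, `simulate_pose_sequence()`):
subject-specific sinusoidal joint kinematics with left/right antiphase,
independent walking bouts as circular time shifts, view-specific noise, and
a planar kinematic chain that turns angle trajectories back into landmark
coordinates. See the methods vignette (`vignettes/gait-matching.Rmd`) for
the model and its limits.

## Worked example

```r
library(gaitmatch)
cohort <- sample_cohort(n_subjects = 8, seed = 42, frames = 100)
dat <- simulate_gait_data(cohort)          # 8 subjects x 11 views, ref + target
fit <- gait_match(dat$reference, dat$target, feature = "angles", part = "whole")
summary(fit)
```

```
<gait_match> feature=angles part=whole | 8 probes x 11 views, 88 gallery entries
Accuracy without voting: 0.7614  (88 probe-view pairs)
Accuracy with voting:    0.8750  (8 probes)

Per-view accuracy:
    0    18    36    54    72    90   108   126   144   162   180
0.750 0.625 0.875 0.625 0.750 0.875 0.625 0.875 0.750 0.625 1.000

Mis-voted probes:
  S06 -> S03
```

At the generator's default view-noise level single views identify roughly
60–75% of probes; pooling the 11 views by majority vote lifts this cohort to
87.5% — one probe (S06) still loses its vote. The same run with
`feature = "correlation"` prints per-view accuracy 0.375 and voted accuracy
0.875: individual views are much weaker with the rank-correlation signature
under heavy angle noise, but the errors decorrelate across views, so voting
recovers most identities.

Pose-file I/O (`read_mediapipe()`, `read_coco18()`, `read_pose_csv()`),
feature export (`write_angle_csv()`, `write_correlation()`) and a
command-line wrapper (`inst/cli/gaitmatch.R` with `simulate`, `extract` and
`run` subcommands) are documented in the help pages.

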