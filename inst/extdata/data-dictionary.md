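# Data dictionary

Coordinate convention everywhere: Cartesian pixels, origin at screen
centre, y increasing upward. Start point (0, -416); targets low
(0, -96), middle (0, 64), high (0, 224). Physical units derive from the
screen's pixel pitch (cm/px), 0.0496 cm/px for the default 43-inch
1920 x 1080 display.

## schedule CSV (write_schedule_csv / run_experiment schedules.csv)

| column          | type    | units | description                                   |
|-----------------|---------|-------|-----------------------------------------------|
| participant     | int     | -     | present only in multi-participant exports     |
| phase           | chr     | -     | baseline, pavlovian, test_safety, test_threat |
| trial_index     | int     | -     | 1-based within phase                          |
| cs_type         | chr     | -     | "CS+" or "CS-"                                |
| position        | chr     | -     | low, middle, high                             |
| target_x_px     | num     | px    | target centre x                               |
| target_y_px     | num     | px    | target centre y                               |
| reinforced      | logical | -     | shock co-termination (pavlovian CS+ only)     |
| pre_stim_s      | num     | s     | pre-stimulus jitter (1-1.5 s)                 |
| iti_s           | num     | s     | inter-trial interval (2-4 s reaching, 12-14 s pavlovian) |
| stim_duration_s | num     | s     | 0.1 reaching phases, 6 pavlovian              |

## trajectory CSV (long format, one row per 100 Hz sample)

| column             | type | units | description                       |
|--------------------|------|-------|-----------------------------------|
| participant        | int  | -     |                                   |
| phase              | chr  | -     | reaching phase label              |
| trial              | int  | -     | trial index within phase          |
| cs_type, position  | chr  | -     | as in the schedule                |
| target_x_px/_y_px  | num  | px    | target centre                     |
| stimulus_offset_ms | num  | ms    | stimulus offset (onset is 0)      |
| t_ms               | num  | ms    | sample time since stimulus onset  |
| x_px, y_px         | num  | px    | cursor position                   |

## SCR signal CSV / events CSV

Signal: `t_s` (s), `conductance_uS` (microsiemens), optional
`participant`. Events: `cs_onset_s` (s from trace start), `cs_type`,
optional `trial_index` and `participant`.

## features CSV (per-trial kinematics)

| column            | units  | description                                  |
|-------------------|--------|----------------------------------------------|
| peak_velocity     | cm/s   | max of the 2-D speed profile                 |
| peak_acceleration | cm/s^2 | max signed speed derivative, onset-offset    |
| peak_deceleration | cm/s^2 | min signed speed derivative (<= 0)           |
| reaction_time     | ms     | stimulus offset to 2%-of-peak onset          |
| accuracy          | cm     | cursor-to-target distance at 2%-of-peak offset |
| onset_index, offset_index, peak_speed_index | - | sample indices      |
| anomalous         | -      | anomaly-screen flag                          |
| anomaly_reasons   | -      | semicolon-separated machine-readable codes   |

## cell_means CSV

`participant, phase, cs_type, position, measure, mean, n_trials` - one
row per participant x cell x measure; `n_trials` counts unflagged
trials; empty cells carry NA means.

## scr_scores CSV

`participant, trial_index, cs_type, amplitude_uS, trough_t_s, peak_t_s,
valid, zero_reason` - amplitude 0 with a reason
(no_deflection / outside_window / too_long / too_small) for invalid
trials; times in s from trace start.
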