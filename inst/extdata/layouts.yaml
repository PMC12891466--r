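# Candidate lead arrangements for layout identification. Leads are listed in
# column-major order (top-to-bottom within each column of panels). Rhythm
# leads are printed as full-width strips below the panel grid and span the
# whole recording.
layouts:
  - name: "3x4+II"
    rows: 3
    cols: 4
    leads: [I, II, III, aVR, aVL, aVF, V1, V2, V3, V4, V5, V6]
    rhythm: [II]
    duration_s: 10
  - name: "3x4"
    rows: 3
    cols: 4
    leads: [I, II, III, aVR, aVL, aVF, V1, V2, V3, V4, V5, V6]
    rhythm: []
    duration_s: 10
  - name: "6x2"
    rows: 6
    cols: 2
    leads: [I, II, III, aVR, aVL, aVF, V1, V2, V3, V4, V5, V6]
    rhythm: []
    duration_s: 10
  - name: "12x1"
    rows: 12
    cols: 1
    leads: [I, II, III, aVR, aVL, aVF, V1, V2, V3, V4, V5, V6]
    rhythm: []
    duration_s: 10
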