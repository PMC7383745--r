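# Diagnostic registry for the 13 Chlorella glyco-groups.
# m/z values are printed reference masses of sodiated, reducing glycans;
# every entry must agree with the package's own mass arithmetic to 0.05 Da.
# 'dominant' diagnostics must reach >= 25 % of the base peak; plain
# presence means >= the 1 % intensity floor.
# oligomannose_me: allowed [min, max] for the per-spectrum maximum methyl
# count on oligomannosidic glycans (~ absent means no constraint).
# sim_oligo_me_max: methylation ceiling used by the spectrum simulator.
# Supporting sets are extensible: only masses printed for the group are
# listed here.
version: "1.0"
groups:
  - name: Kei
    required:
      - {os: os3231, mz: 1343.46, dominant: true}
    supporting: []
    forbidden:
      - {os: os3230, mz: 1329.4}
      - {os: os4211, mz: 1241.4}
    oligomannose_me: ~
    sim_oligo_me_max: 1
    notes: >
      Defined by the dominant os3231 at 1343.46; LIFT shows a free GlcNAc-1
      but a substituted GlcNAc-2. A dominant pentose series (1329.4) points
      to the Sol/Jar family instead.
  - name: Hel
    required:
      - {os: os4223, mz: 1401.5, dominant: true}
    supporting:
      - {os: os4222, mz: 1387.5}
      - {os: os4221, mz: 1373.5}
    forbidden: []
    oligomannose_me: ~
    sim_oligo_me_max: 2
    ladder: {top_os: os4223, steps: 2}
    notes: >
      Main glycan os4223 preceded by a 14-Da methylation ladder down to
      os4221; unsubstituted chitobiose core. Pattern of C. sorokiniana type
      strains.
  - name: Jos
    required:
      - {os: os4221, mz: 1373.5, dominant: true}
    supporting:
      - {os: os3221, mz: 1211.4}
    forbidden:
      - {os: os4223, mz: 1401.5}
      - {os: os4213, mz: 1269.5}
    oligomannose_me: ~
    sim_oligo_me_max: 2
    notes: >
      Shares os4221 with Hel but as the dominant peak and with a different
      LIFT pattern; a dominant 1401.5 (Hel) or 1269.5 (Ori) excludes Jos.
      A tentative 'Wel' subtype (methylated oligomannose, 1211.3 etc.) is
      noted here but is not a separate registry entry.
  - name: Ori
    required:
      - {os: os4213, mz: 1269.5, dominant: true}
    supporting:
      - {os: os4221, mz: 1373.5}
      - {os: os3221, mz: 1211.4}
    forbidden: []
    oligomannose_me: ~
    sim_oligo_me_max: 1
    notes: >
      Dominant core-fucosylated os4213 (released by PNGase A only); may be a
      catchment basin for more than one strain - mixtures are flagged, not
      split into extra groups.
  - name: Raa
    required:
      - {os: os2221, mz: 1049.4, dominant: true}
    supporting: []
    forbidden: []
    oligomannose_me: [0, 0]
    sim_oligo_me_max: 0
    notes: >
      Dominant os2221 with unmethylated oligomannosidic glycans; pentose on
      GlcNAc-2 is arabinose.
  - name: Now
    required:
      - {os: os2221, mz: 1049.4, dominant: true}
    supporting: []
    forbidden: []
    oligomannose_me: [1, 7]
    sim_oligo_me_max: 2
    notes: >
      Same dominant mass as Raa but with methylated oligomannose; the
      pentose is xylose. MS1-separable from Raa only via the methylation
      ceiling.
  - name: Sun
    required:
      - {os: os3312, mz: 1296.5, dominant: true}
    supporting:
      - {os: os3205, mz: 1003.4}
      - {os: os5332, mz: 1884.7}
    forbidden: []
    oligomannose_me: ~
    sim_oligo_me_max: 0
    notes: >
      Third N-acetylhexosamine (4-O-methyl GlcNAc) renders the group unique;
      LIFT shows loss of a methylated GlcNAc from an unsubstituted core.
  - name: Sol
    required:
      - {os: os3220, mz: 1197.4, dominant: true}
      - {os: os3230, mz: 1329.4, dominant: true}
      - {os: os4230, mz: 1491.5, dominant: true}
      - {os: os5300, mz: 1460.5, dominant: false}
    supporting:
      - {os: os3231, mz: 1343.5}
      - {os: os3221, mz: 1211.4}
    forbidden:
      - {os: os9213, mz: 2079.7}
      - {os: os4211, mz: 1241.4}
    oligomannose_me: [1, 7]
    sim_oligo_me_max: 3
    notes: >
      Pentose series os3220/os3230/os4230 with methylated oligomannose and
      the Man5Gn peak at 1460.5 (confirmed by the core
      alpha-1,6-fucosyltransferase substrate test).
  - name: Jar
    required:
      - {os: os3220, mz: 1197.4, dominant: true}
      - {os: os3230, mz: 1329.4, dominant: true}
      - {os: os4230, mz: 1491.5, dominant: true}
    supporting:
      - {os: os3231, mz: 1343.5}
      - {os: os3221, mz: 1211.4}
    forbidden:
      - {os: os5300, mz: 1460.5}
      - {os: os9213, mz: 2079.7}
      - {os: os4211, mz: 1241.4}
    oligomannose_me: [0, 0]
    sim_oligo_me_max: 0
    notes: >
      Seemingly identical to Sol apart from the lack of 1460.5 and the
      unmethylated oligomannose.
  - name: Gov
    required:
      - {os: os3230, mz: 1329.4, dominant: true}
      - {os: os4230, mz: 1491.5, dominant: true}
    supporting:
      - {os: os3231, mz: 1343.5}
      - {os: os3220, mz: 1197.4}
    forbidden:
      - {os: os5300, mz: 1460.5}
      - {os: os9213, mz: 2079.7}
      - {os: os4211, mz: 1241.4}
    oligomannose_me: [1, 3]
    sim_oligo_me_max: 2
    notes: >
      Jar-type series with pronounced oligomannose methylation, up to three
      methyl groups per glycan.
  - name: Ama
    required:
      - {os: os3230, mz: 1329.4, dominant: true}
      - {os: os4230, mz: 1491.5, dominant: true}
    supporting:
      - {os: os3231, mz: 1343.5}
      - {os: os3220, mz: 1197.4}
    forbidden:
      - {os: os5300, mz: 1460.5}
      - {os: os9213, mz: 2079.7}
      - {os: os4211, mz: 1241.4}
    oligomannose_me: [4, 7]
    sim_oligo_me_max: 7
    notes: >
      Jar-type series with extremely high oligomannose methylation, up to
      seven methyl groups per glycan.
  - name: Asp
    required:
      - {os: os9213, mz: 2079.7, dominant: true}
      - {os: "os[10]213", mz: 2241.8, dominant: true}
    supporting:
      - {os: os3230, mz: 1329.4}
      - {os: os3231, mz: 1343.5}
      - {os: os4230, mz: 1491.5}
    forbidden: []
    oligomannose_me: ~
    sim_oligo_me_max: 2
    notes: >
      Large methylated glycans os9213 and os[10]213. The printed 2565.7 for
      os[12]213 disagrees with the residue arithmetic (computed 2565.9) and
      is deliberately not a diagnostic.
  - name: Pit
    required:
      - {os: os4211, mz: 1241.4, dominant: true}
      - {os: os4212, mz: 1255.4, dominant: true}
    supporting:
      - {os: os3230, mz: 1329.4}
      - {os: os3231, mz: 1343.5}
      - {os: os4230, mz: 1491.5}
    forbidden: []
    oligomannose_me: ~
    sim_oligo_me_max: 1
    notes: >
      Small xylose-containing glycans os4211/os4212 with methylated mannose,
      no galactose, unsubstituted chitobiose.
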