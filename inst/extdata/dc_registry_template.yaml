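# Diagnostic-concentration registry template.
#
# PLACEHOLDER VALUES ONLY. Diagnostic (discriminating) concentrations are
# species- and insecticide-specific and must be taken from the current WHO
# documentation for your assay type; replace every value below and record
# its source. readout_hours defaults to 24; slow-acting compounds such as
# chlorfenapyr are read at 72 h.
"Aedes albopictus":
  deltamethrin:
    diagnostic_concentration: 0.03   # PLACEHOLDER - replace with WHO value
    units: "%"
    assay_type: tube
    readout_hours: 24
    source: "PLACEHOLDER - cite your WHO reference"
  chlorfenapyr:
    diagnostic_concentration: 100.0  # PLACEHOLDER - replace with WHO value
    units: "ug/bottle"
    assay_type: bottle
    readout_hours: 72
    source: "PLACEHOLDER - cite your WHO reference"
"Aedes aegypti":
  deltamethrin:
    diagnostic_concentration: 0.03   # PLACEHOLDER - replace with WHO value
    units: "%"
    assay_type: tube
    readout_hours: 24
    source: "PLACEHOLDER - cite your WHO reference"
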