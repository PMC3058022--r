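# Canonical units per variable and accepted input units.
# canonical value = value * factor + offset (offset defaults to 0).
# Conventional clinical units are canonical because the published point
# tables are expressed in them.
map:              {canonical: mmHg, accepted: {mmHg: {factor: 1}, kPa: {factor: 7.50062}}}
sbp:              {canonical: mmHg, accepted: {mmHg: {factor: 1}, kPa: {factor: 7.50062}}}
heart_rate:       {canonical: /min, accepted: {/min: {factor: 1}, bpm: {factor: 1}}}
cvp:              {canonical: mmHg, accepted: {mmHg: {factor: 1}, cmH2O: {factor: 0.73556}}}
lactate:          {canonical: mmol/L, accepted: {mmol/L: {factor: 1}, mg/dL: {factor: 0.11101}}}
pao2:             {canonical: mmHg, accepted: {mmHg: {factor: 1}, kPa: {factor: 7.50062}}}
fio2:             {canonical: fraction, accepted: {fraction: {factor: 1}, '%': {factor: 0.01}}}
paco2:            {canonical: mmHg, accepted: {mmHg: {factor: 1}, kPa: {factor: 7.50062}}}
respiratory_rate: {canonical: /min, accepted: {/min: {factor: 1}}}
ph:               {canonical: pH, accepted: {pH: {factor: 1}}}
creatinine:       {canonical: mg/dL, accepted: {mg/dL: {factor: 1}, umol/L: {factor: 0.011312217194570136}}}
urea:             {canonical: mmol/L, accepted: {mmol/L: {factor: 1}, mg/dL: {factor: 0.357}, g/L: {factor: 16.65}}}
urine_output:     {canonical: mL, accepted: {mL: {factor: 1}, L: {factor: 1000}}}
bilirubin:        {canonical: mg/dL, accepted: {mg/dL: {factor: 1}, umol/L: {factor: 0.058479532163742687}}}
platelets:        {canonical: 10^3/uL, accepted: {10^3/uL: {factor: 1}, 10^9/L: {factor: 1}}}
leukocytes:       {canonical: 10^3/uL, accepted: {10^3/uL: {factor: 1}, 10^9/L: {factor: 1}}}
hematocrit:       {canonical: '%', accepted: {'%': {factor: 1}, fraction: {factor: 100}}}
sodium:           {canonical: mmol/L, accepted: {mmol/L: {factor: 1}, mEq/L: {factor: 1}}}
potassium:        {canonical: mmol/L, accepted: {mmol/L: {factor: 1}, mEq/L: {factor: 1}}}
bicarbonate:      {canonical: mmol/L, accepted: {mmol/L: {factor: 1}, mEq/L: {factor: 1}}}
temperature:      {canonical: degC, accepted: {degC: {factor: 1}, degF: {factor: 0.5555556, offset: -17.7777778}}}
gcs:              {canonical: points, accepted: {points: {factor: 1}}}
neurologic_state: {canonical: ordinal, accepted: {ordinal: {factor: 1}}}
mech_ventilation: {canonical: flag, accepted: {flag: {factor: 1}}}
iabp:             {canonical: flag, accepted: {flag: {factor: 1}}}
vad:              {canonical: flag, accepted: {flag: {factor: 1}}}
dialysis:         {canonical: flag, accepted: {flag: {factor: 1}}}
catecholamine_dose_class: {canonical: class, accepted: {class: {factor: 1}}}
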