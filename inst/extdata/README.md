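Synthetic mass-attenuation tables (1 keV grid, 10-120 keV) generated from the
package's two-component analytic model (photoelectric E^-3 + Klein-Nishina
Compton shape), anchored near tabulated values for the real materials; the
walnut shell/pulp entries are entirely synthetic stand-ins. Not measured
data. Replace with measured tables in the same TSV format via
read_material_table() if available.
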