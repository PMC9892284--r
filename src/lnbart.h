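#ifndef LNBART_H
#define LNBART_H

double pg1_draw(double z);
double pg_mean(double b, double z);
double pg_var(double b, double z);
double pg_draw_one(double b, double z, int threshold);

#endif
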