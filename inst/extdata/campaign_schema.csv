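file,column,type,unit,description
series.csv,chamber_id,string,,unique chamber identifier (site_status_microtopography_rNN)
series.csv,site,string,,monitoring site name
series.csv,status,string,,palm status stratum: live or cut
series.csv,microtopography,string,,hummock or hollow
series.csv,replicate,integer,,replicate chamber number within the stratum
series.csv,date,date,,campaign date (YYYY-MM-DD)
series.csv,t_min,numeric,min,sampling time since chamber closure
series.csv,conc_ppb,numeric,ppb,headspace mixing ratio
series.csv,gas,string,,N2O or CH4
series.csv,air_temp_C,numeric,degC,air temperature at deployment
series.csv,soil_temp_C,numeric,degC,soil temperature (top 10 cm)
series.csv,pressure_kPa,numeric,kPa,atmospheric pressure at deployment
series.csv,headspace_m,numeric,m,chamber headspace height (volume/area)
drivers.csv,wt,numeric,cm,water table level relative to soil surface (positive above)
drivers.csv,wfps,numeric,%,water-filled pore space
drivers.csv,air_t,numeric,degC,air temperature
drivers.csv,soil_t,numeric,degC,soil temperature
drivers.csv,co2,numeric,kg C ha-1 day-1,soil respiration
drivers.csv,no3,numeric,mg N kg-1 d.m.,soil nitrate content
drivers.csv,net_nit,numeric,mg N kg-1 d.m. day-1,net nitrification rate
drivers.csv,precip,numeric,mm month-1,monthly precipitation
truth.csv,true_flux,numeric,g N or g C ha-1 day-1,generative true flux of the chamber-month
truth.csv,anomaly,string,,none / leak_point / nonlinear
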